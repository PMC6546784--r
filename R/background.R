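# Derive a per-stream seed below 2^31 from a base seed and stream index,
# so draws for one element/set never perturb another's.
derive_seed <- function(seed, stream) {
  (((seed %% 2147483647) * 48271) + stream * 2654435761 + 11) %% 2147483563
}

# Stable per-element stream id from the element's own coordinates, so the
# substream survives reordering or adding/removing other elements.
element_stream <- function(chrom, start, end) {
  ch <- vapply(chrom, function(x) {
    sum(utf8ToInt(x) * 31^(seq_along(utf8ToInt(x)) %% 8)) %% 1048573
  }, numeric(1))
  (ch + start * 131 + (end - start) * 9176) %% 2147483563
}

# GC fraction for same-length windows at `starts` on one chromosome
# sequence; windows containing only ambiguous bases return NaN.
gc_at <- function(seq, starts, len) {
  v <- Biostrings::Views(seq, start = starts + 1, end = starts + len)
  counts <- Biostrings::letterFrequency(v, letters = c("A", "C", "G", "T"))
  denom <- rowSums(counts)
  (counts[, "C"] + counts[, "G"]) / denom
}

#' Sample GC- and length-matched control regions
#'
#' For each element, draws `reps` random regions on the same chromosome
#' with identical length and GC content within `gc_tol` (rejection sampling
#' over uniform start positions). Controls may overlap elements or each
#' other; only exact duplicate `(chrom, start, end)` triples are removed
#' after pooling across all elements. This is the background used to fit
#' the chromatin-contact null.
#'
#' @param elements Interval tibble (a `name` column labels sources;
#'   otherwise rows are labelled `el<i>`).
#' @param genome A named [Biostrings::DNAStringSet].
#' @param reps Controls per element (default 40).
#' @param gc_tol Maximum absolute GC difference (default 0.05, i.e. < 5
#'   percentage points).
#' @param seed Integer seed; each element gets an independent substream.
#' @param max_attempts Rejection-sampling budget per draw; on exhaustion the
#'   nearest-GC candidate seen is kept and the draw flagged `relaxed`.
#' @return Tibble of deduplicated controls with columns `source`,
#'   `replicate`, `chrom`, `start`, `end`, `gc`, `relaxed`, plus attributes
#'   `total_drawn` (draws before dedup), `n_after_dedup` and `n_relaxed`.
#' @export
sample_gc_length_matched <- function(elements, genome, reps = 40, gc_tol = 0.05,
                                     seed = 1, max_attempts = 10000) {
  stopifnot(reps >= 1, gc_tol > 0, gc_tol < 1)
  elements <- as_intervals(elements)
  src_gc <- gc_content(elements, genome)
  sizes <- genome_sizes(genome)
  src_names <- if ("name" %in% names(elements)) elements$name else
    paste0("el", seq_len(nrow(elements)))
  streams <- element_stream(elements$chrom, elements$start, elements$end)
  res <- vector("list", nrow(elements))
  for (i in seq_len(nrow(elements))) {
    set.seed(derive_seed(seed, streams[i]))
    chr <- elements$chrom[i]
    len <- elements$end[i] - elements$start[i]
    max_start <- sizes[[chr]] - len
    if (max_start < 0) stop("element longer than its chromosome: row ", i)
    seq <- genome[[chr]]
    acc_start <- numeric(0)
    acc_gc <- numeric(0)
    relaxed <- logical(0)
    attempts <- 0
    best_start <- NA_real_; best_gc <- NA_real_; best_diff <- Inf
    while (length(acc_start) < reps && attempts < max_attempts * reps) {
      need <- reps - length(acc_start)
      batch <- max(4L * need, 64L)
      starts <- floor(stats::runif(batch, 0, max_start + 1))
      gcs <- gc_at(seq, starts, len)
      attempts <- attempts + batch
      diff <- abs(gcs - src_gc[i])
      ok <- which(is.finite(diff) & diff < gc_tol)
      if (length(ok) > 0) {
        take <- ok[seq_len(min(need, length(ok)))]
        acc_start <- c(acc_start, starts[take])
        acc_gc <- c(acc_gc, gcs[take])
        relaxed <- c(relaxed, rep(FALSE, length(take)))
      }
      cand <- which.min(ifelse(is.finite(diff), diff, Inf))
      if (length(cand) == 1 && is.finite(diff[cand]) && diff[cand] < best_diff) {
        best_diff <- diff[cand]; best_start <- starts[cand]; best_gc <- gcs[cand]
      }
    }
    n_short <- reps - length(acc_start)
    if (n_short > 0) {
      warning("element ", src_names[i], ": GC match not found for ", n_short,
              " draw(s) within attempt budget; using nearest-GC candidate")
      acc_start <- c(acc_start, rep(best_start, n_short))
      acc_gc <- c(acc_gc, rep(best_gc, n_short))
      relaxed <- c(relaxed, rep(TRUE, n_short))
    }
    res[[i]] <- tibble::tibble(
      source = src_names[i], replicate = seq_len(reps), chrom = chr,
      start = acc_start, end = acc_start + len, gc = acc_gc, relaxed = relaxed
    )
  }
  pooled <- dplyr::bind_rows(res)
  total_drawn <- nrow(pooled)
  out <- dplyr::distinct(pooled, .data$chrom, .data$start, .data$end,
                         .keep_all = TRUE)
  attr(out, "total_drawn") <- total_drawn
  attr(out, "n_after_dedup") <- nrow(out)
  attr(out, "n_relaxed") <- sum(pooled$relaxed)
  out
}

#' Sample size- and conservation-matched region sets
#'
#' Draws `n_sets` independent region sets, each with one control per
#' element of the same length whose mean conservation score lies within
#' `match_tol` of the source element's. Placement is genome-wide
#' (chromosomes weighted by length). Used as the permutation null for
#' annotation-overlap odds ratios.
#'
#' @param elements Interval tibble.
#' @param track Conservation tibble (see [as_conservation()]).
#' @param chrom_sizes Named chromosome lengths.
#' @param n_sets Number of matched sets to draw.
#' @param seed Integer seed; each set is an independent substream.
#' @param match_tol Mean-score matching tolerance (default 0.05).
#' @param max_rounds Rejection rounds per set before falling back to the
#'   nearest-score candidate for unmatched elements.
#' @return Tibble with columns `set`, `source`, `chrom`, `start`, `end`,
#'   `score`, `relaxed`; attribute `n_relaxed` counts fallback draws.
#' @export
sample_conservation_matched <- function(elements, track, chrom_sizes, n_sets,
                                        seed = 1, match_tol = 0.05,
                                        max_rounds = 200) {
  stopifnot(n_sets >= 1)
  elements <- as_intervals(elements)
  sizes <- as_chrom_sizes(chrom_sizes)
  ci <- conservation_index(track)
  src_score <- mean_conservation(elements, ci)
  lens <- elements$end - elements$start
  src_names <- if ("name" %in% names(elements)) elements$name else
    paste0("el", seq_len(nrow(elements)))
  chroms <- names(sizes)
  chr_w <- sizes / sum(sizes)
  n <- nrow(elements)
  track_tbl <- as_conservation(track)
  sets <- vector("list", n_sets)
  n_relaxed_total <- 0
  for (s in seq_len(n_sets)) {
    set.seed(derive_seed(seed, 1000000 + s))
    done_chr <- character(n); done_start <- numeric(n); done_score <- numeric(n)
    matched <- rep(FALSE, n)
    best_diff <- rep(Inf, n)
    round <- 0
    while (any(!matched) && round < max_rounds) {
      round <- round + 1
      pend <- which(!matched)
      # proposal mixture: uniform placement, plus placement anchored on a
      # scored run of the track (high-score sources are rarely matchable
      # by uniform draws when scored territory is sparse)
      on_run <- stats::runif(length(pend)) < 0.5 & nrow(track_tbl) > 0
      chr <- sample(chroms, length(pend), replace = TRUE, prob = chr_w)
      ri <- sample.int(nrow(track_tbl), length(pend), replace = TRUE)
      chr[on_run] <- track_tbl$chrom[ri[on_run]]
      max_start <- sizes[chr] - lens[pend]
      ok_len <- max_start >= 0
      start <- floor(stats::runif(length(pend), 0, pmax(max_start, 0) + 1))
      run_lo <- pmax(track_tbl$start[ri] - lens[pend], 0)
      run_hi <- pmin(pmax(track_tbl$end[ri] - 1, run_lo + 1),
                     pmax(max_start, 0))
      run_hi <- pmax(run_hi, run_lo)
      start[on_run] <- floor(stats::runif(sum(on_run), run_lo[on_run],
                                          run_hi[on_run] + 1))
      start <- pmin(start, pmax(max_start, 0))
      cand <- tibble::tibble(chrom = chr, start = start, end = start + lens[pend])
      sc <- mean_conservation(cand, ci)
      diff <- abs(sc - src_score[pend])
      diff[!ok_len] <- Inf
      better <- diff < best_diff[pend]
      upd <- pend[better]
      done_chr[upd] <- chr[better]
      done_start[upd] <- start[better]
      done_score[upd] <- sc[better]
      best_diff[upd] <- diff[better]
      matched[pend] <- best_diff[pend] <= match_tol
    }
    n_relaxed_total <- n_relaxed_total + sum(!matched)
    sets[[s]] <- tibble::tibble(
      set = s, source = src_names, chrom = done_chr, start = done_start,
      end = done_start + lens, score = done_score, relaxed = !matched
    )
  }
  if (n_relaxed_total > 0) {
    warning(n_relaxed_total,
            " draw(s) could not meet the conservation tolerance; ",
            "nearest-score candidates used")
  }
  out <- dplyr::bind_rows(sets)
  attr(out, "n_relaxed") <- n_relaxed_total
  attr(out, "n_sets") <- n_sets
  out
}
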