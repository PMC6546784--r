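#' Validate a conservation track
#'
#' A conservation track is a tibble of non-overlapping scored runs
#' (`chrom`, `start`, `end`, `score`) with scores in \[0, 1\]; positions not
#' covered by any run have score 0 (the bedGraph convention for
#' phastCons-like tracks).
#'
#' @param x A data frame with columns `chrom`, `start`, `end`, `score`.
#' @return Sorted, validated tibble.
#' @export
as_conservation <- function(x) {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end", "score") %in% names(x)))
  x <- as_intervals(x)
  if (any(x$score < 0 | x$score > 1)) stop("conservation scores must lie in [0, 1]")
  for (chr in unique(x$chrom)) {
    sub <- x[x$chrom == chr, ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)])) {
      stop("overlapping conservation runs on ", chr)
    }
  }
  x
}

#' Read a bedGraph conservation track
#' @param path Path to 4-column tab-separated bedGraph (no header).
#' @return Conservation tibble (see [as_conservation()]).
#' @export
read_bedgraph <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "score"),
                        col_types = "cddd", progress = FALSE)
  as_conservation(df)
}

#' Write a conservation track as bedGraph
#' @param track Conservation tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- as_conservation(track)[c("chrom", "start", "end", "score")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Call conserved regions from a conservation track
#'
#' Returns maximal runs of bases with score strictly above `threshold`,
#' keeping only runs strictly longer than `min_len` (regions "larger than"
#' the minimum length, with score above the cutoff).
#'
#' @param track Conservation tibble.
#' @param min_len Minimum region length in bp (exclusive; default 20).
#' @param threshold Score cutoff (exclusive; default 0.40).
#' @return Interval tibble of conserved regions.
#' @export
call_conserved_regions <- function(track, min_len = 20, threshold = 0.40) {
  track <- as_conservation(track)
  above <- track[track$score > threshold, c("chrom", "start", "end")]
  if (nrow(above) == 0) {
    return(tibble::tibble(chrom = character(0), start = numeric(0), end = numeric(0)))
  }
  merged <- above |>
    dplyr::group_by(.data$chrom) |>
    dplyr::reframe(collapse_intervals(dplyr::pick("start", "end")))
  out <- merged[merged$end - merged$start > min_len, ]
  as_intervals(out)
}

# Precompute per-chromosome cumulative score integrals for O(1) interval
# mean-score queries (gaps contribute 0).
conservation_index <- function(track) {
  track <- as_conservation(track)
  idx <- lapply(split(track, track$chrom), function(sub) {
    sub <- sub[order(sub$start), ]
    w <- sub$end - sub$start
    list(starts = sub$start, ends = sub$end, scores = sub$score,
         cum = c(0, cumsum(sub$score * w)))
  })
  structure(idx, class = "conservation_index")
}

# Cumulative integral of the track up to position `pos` (vectorized).
cons_integral <- function(ci_chr, pos) {
  i <- findInterval(pos, ci_chr$starts)
  out <- numeric(length(pos))
  hit <- i > 0
  ih <- i[hit]
  inside <- pmin(pmax(pos[hit] - ci_chr$starts[ih], 0),
                 ci_chr$ends[ih] - ci_chr$starts[ih])
  out[hit] <- ci_chr$cum[ih] + ci_chr$scores[ih] * inside
  out
}

#' Mean conservation score of intervals
#'
#' Mean per-base score over each interval, counting uncovered bases as 0.
#'
#' @param intervals Interval tibble.
#' @param track Conservation tibble, or a prebuilt index from
#'   `conservation_index()`.
#' @return Numeric vector of mean scores.
#' @export
mean_conservation <- function(intervals, track) {
  ci <- if (inherits(track, "conservation_index")) track else conservation_index(track)
  intervals <- tibble::as_tibble(intervals)
  out <- numeric(nrow(intervals))
  for (chr in unique(intervals$chrom)) {
    sel <- which(intervals$chrom == chr)
    if (!chr %in% names(ci)) { out[sel] <- 0; next }
    s <- intervals$start[sel]; e <- intervals$end[sel]
    out[sel] <- (cons_integral(ci[[chr]], e) - cons_integral(ci[[chr]], s)) / (e - s)
  }
  out
}
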