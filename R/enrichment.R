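#' Binomial (region-based) enrichment of elements in an annotation
#'
#' GREAT-style test: with `p` the fraction of the genome covered by the
#' annotation (merged span / genome length), `n` the number of elements and
#' `s` the number of elements overlapping the annotation by at least 1 bp,
#' the p-value is the upper binomial tail `Pr(k >= s | n, p)` and fold
#' enrichment is `(s/n)/p`.
#'
#' @param elements Interval tibble (non-empty).
#' @param annotation Interval tibble of annotation peaks.
#' @param genome_length Total genome length in bp.
#' @return One-row tibble: `method`, `n`, `s`, `p_genome`, `fold`,
#'   `p.value`.
#' @export
binomial_enrichment <- function(elements, annotation, genome_length) {
  elements <- as_intervals(elements)
  if (nrow(elements) == 0) stop("empty element set")
  annotation <- as_intervals(annotation)
  span <- merged_span(annotation)
  stopifnot(genome_length >= span)
  p <- span / genome_length
  n <- nrow(elements)
  s <- sum(overlaps_any(elements, annotation))
  pv <- if (s == 0) 1 else stats::pbinom(s - 1, n, p, lower.tail = FALSE)
  tibble::tibble(method = "binomial", n = n, s = s, p_genome = p,
                 fold = (s / n) / p, p.value = pv)
}

# 2x2 overlap table: elements/background (rows) x overlap/not (columns).
contingency_counts <- function(elements, annotation, background) {
  A <- sum(overlaps_any(elements, annotation))
  B <- sum(overlaps_any(background, annotation))
  c(A = A, B = B, C = nrow(elements) - A, D = nrow(background) - B)
}

# Sample OR with Woolf log-OR CI; Haldane +0.5 applied to the CI (and a
# flag raised) when any cell is zero.
or_with_ci <- function(A, B, C, D, conf = 0.95) {
  zero_cell <- any(c(A, B, C, D) == 0)
  or <- (A * D) / (B * C)   # may be 0, Inf, or NaN for doubly-degenerate cells
  a <- A; b <- B; cc <- C; d <- D
  if (zero_cell) { a <- A + 0.5; b <- B + 0.5; cc <- C + 0.5; d <- D + 0.5 }
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  lo <- exp(log((a * d) / (b * cc)) - z * se)
  hi <- exp(log((a * d) / (b * cc)) + z * se)
  list(odds_ratio = or, conf.low = lo, conf.high = hi, haldane = zero_cell)
}

#' Fisher's exact enrichment against a matched background set
#'
#' Builds the 2x2 table A = elements overlapping the annotation, B =
#' background regions overlapping, C/D their complements, and reports the
#' sample odds ratio `AD/BC`, a Woolf 95% CI (Haldane-corrected and
#' flagged when a cell is zero) and the two-sided exact p-value.
#'
#' @param elements,annotation,background Interval tibbles; `background` is
#'   typically conserved regions from [call_conserved_regions()].
#' @return One-row tibble: `method`, `A`, `B`, `C`, `D`, `odds_ratio`,
#'   `conf.low`, `conf.high`, `p.value`, `haldane`.
#' @export
fisher_conserved <- function(elements, annotation, background) {
  elements <- as_intervals(elements)
  background <- as_intervals(background)
  if (nrow(background) == 0) stop("empty background set")
  ct <- contingency_counts(elements, as_intervals(annotation), background)
  margins <- c("elements (A+C)" = ct[["A"]] + ct[["C"]],
               "background (B+D)" = ct[["B"]] + ct[["D"]],
               "overlapping (A+B)" = ct[["A"]] + ct[["B"]],
               "non-overlapping (C+D)" = ct[["C"]] + ct[["D"]])
  if (any(margins == 0)) {
    stop("degenerate contingency table: zero margin ",
         paste(names(margins)[margins == 0], collapse = ", "))
  }
  pv <- stats::fisher.test(matrix(ct, nrow = 2, byrow = TRUE))$p.value
  ci <- or_with_ci(ct[["A"]], ct[["B"]], ct[["C"]], ct[["D"]])
  tibble::tibble(method = "fisher_conserved",
                 A = ct[["A"]], B = ct[["B"]], C = ct[["C"]], D = ct[["D"]],
                 odds_ratio = ci$odds_ratio, conf.low = ci$conf.low,
                 conf.high = ci$conf.high, p.value = pv, haldane = ci$haldane)
}

#' Permutation odds-ratio distribution from matched region sets
#'
#' Recomputes the [fisher_conserved()] contingency table once per matched
#' set (substituting the set for the elements) to obtain a null OR
#' distribution, and reports the empirical p-value
#' `(1 + #\{null OR >= observed\}) / (n_used + 1)`.
#'
#' @param elements,annotation,background As in [fisher_conserved()].
#' @param matched_sets Either the tibble returned by
#'   [sample_conservation_matched()] (split on its `set` column) or a list
#'   of interval tibbles.
#' @return An `or_distribution` object: list with `observed` (the
#'   [fisher_conserved()] row), `null_or`, `p_empirical`, `n_sets`,
#'   `n_degenerate`. Has [generics::tidy()]/[generics::glance()] methods.
#' @export
permutation_or <- function(elements, annotation, matched_sets, background) {
  observed <- fisher_conserved(elements, annotation, background)
  annotation <- as_intervals(annotation)
  background <- as_intervals(background)
  if (is.data.frame(matched_sets)) {
    stopifnot("set" %in% names(matched_sets))
    pooled <- tibble::as_tibble(matched_sets)
  } else {
    pooled <- dplyr::bind_rows(
      purrr::imap(matched_sets, ~ dplyr::mutate(tibble::as_tibble(.x), set = .y)))
  }
  n_sets <- length(unique(pooled$set))
  if (n_sets < 2) stop("need at least 2 matched sets")
  hit <- overlaps_any(pooled[c("chrom", "start", "end")], annotation)
  per_set <- pooled |>
    dplyr::mutate(hit = hit) |>
    dplyr::summarise(A = sum(.data$hit), n = dplyr::n(), .by = "set")
  B <- sum(overlaps_any(background, annotation))
  D <- nrow(background) - B
  A <- per_set$A
  C <- per_set$n - A
  null_or <- (A * D) / (B * C)
  degenerate <- is.nan(null_or)  # 0/0 tables carry no ordering information
  null_or <- null_or[!degenerate]
  p_emp <- (1 + sum(null_or >= observed$odds_ratio)) / (length(null_or) + 1)
  structure(list(observed = observed, null_or = null_or,
                 p_empirical = p_emp, n_sets = n_sets,
                 n_degenerate = sum(degenerate)),
            class = "or_distribution")
}

#' @export
print.or_distribution <- function(x, ...) {
  cat("Permutation OR distribution:", length(x$null_or), "null sets\n")
  cat(sprintf("  observed OR = %.3g, empirical p = %.3g (%d degenerate skipped)\n",
              x$observed$odds_ratio, x$p_empirical, x$n_degenerate))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy or_distribution
#' @export
tidy.or_distribution <- function(x, ...) {
  tibble::tibble(set = seq_along(x$null_or), null_or = x$null_or)
}

#' @method glance or_distribution
#' @export
glance.or_distribution <- function(x, ...) {
  tibble::tibble(observed_or = x$observed$odds_ratio,
                 p_empirical = x$p_empirical,
                 n_sets = x$n_sets, n_degenerate = x$n_degenerate,
                 fisher_p = x$observed$p.value)
}
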