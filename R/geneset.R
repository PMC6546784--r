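#' Background gene list from windows around elements
#'
#' Returns the genes whose body overlaps the 1 Mb (by default) flanking
#' window of at least one element — the windowed background used for gene
#' ontology style enrichment of element-associated genes.
#'
#' @param elements Interval tibble.
#' @param genes A `gene_model` tibble.
#' @param window Flank width in bp on each side (default 1e6).
#' @return Sorted character vector of gene ids.
#' @export
build_window_background <- function(elements, genes, window = 1e6) {
  stopifnot(window > 0)
  elements <- as_intervals(elements)
  expanded <- tibble::tibble(chrom = elements$chrom,
                             start = pmax(elements$start - window, 0),
                             end = elements$end + window)
  bodies <- tibble::tibble(chrom = genes$chrom, start = genes$start,
                           end = genes$end, name = genes$gene_id)
  hits <- overlap_pairs(as_intervals(expanded), as_intervals(bodies))
  bodies_sorted <- as_intervals(bodies)
  sort(unique(bodies_sorted$name[hits$b_index]))
}

#' Gene-set enrichment by logistic regression with a coding-length covariate
#'
#' Fits `target ~ in_set (+ log(cds_length + 1))` by binomial GLM over a
#' declared background of genes. The odds ratio is the exponentiated
#' set-membership coefficient with a Wald two-sided p-value; without the
#' covariate this equals the sample 2x2 odds ratio. Complete separation is
#' detected and flagged (infinite OR with a warning) rather than silently
#' reported.
#'
#' @param annotation Tibble with one row per background gene: columns
#'   `gene_id`, `target` (0/1: element-associated), `in_set` (0/1: curated
#'   list member) and, when `use_covariate = TRUE`, `cds_length`.
#' @param use_covariate Adjust for log-transformed coding-sequence length.
#' @return One-row tibble: `odds_ratio`, `conf.low`, `conf.high`,
#'   `p.value`, `n`, counts `A`-`D`, `method`, `separated` flag.
#' @export
logistic_enrichment <- function(annotation, use_covariate = FALSE) {
  annotation <- tibble::as_tibble(annotation)
  stopifnot(all(c("gene_id", "target", "in_set") %in% names(annotation)),
            all(annotation$target %in% 0:1), all(annotation$in_set %in% 0:1))
  if (nrow(annotation) < 50) stop("background must contain at least 50 genes")
  if (length(unique(annotation$target)) < 2) stop("target flag does not vary")
  if (length(unique(annotation$in_set)) < 2) stop("set flag does not vary")
  A <- sum(annotation$target == 1 & annotation$in_set == 1)
  B <- sum(annotation$target == 0 & annotation$in_set == 1)
  C <- sum(annotation$target == 1 & annotation$in_set == 0)
  D <- sum(annotation$target == 0 & annotation$in_set == 0)
  covariate_used <- use_covariate
  if (use_covariate) {
    stopifnot("cds_length" %in% names(annotation),
              all(annotation$cds_length >= 0))
    if (stats::sd(annotation$cds_length) == 0) covariate_used <- FALSE
  }
  if (covariate_used) {
    fml <- target ~ in_set + log(cds_length + 1)
  } else {
    fml <- target ~ in_set
  }
  fit <- suppressWarnings(
    stats::glm(fml, data = annotation, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  sm <- summary(fit)$coefficients
  beta <- sm["in_set", "Estimate"]
  se <- sm["in_set", "Std. Error"]
  separated <- A == 0 || B == 0 || C == 0 || D == 0 || abs(beta) > 15
  if (separated) {
    warning("separation detected: odds ratio unbounded")
    or <- if (beta > 0) Inf else 0
    lo <- NA_real_; hi <- NA_real_; pv <- sm["in_set", "Pr(>|z|)"]
  } else {
    or <- exp(beta)
    lo <- exp(beta - stats::qnorm(0.975) * se)
    hi <- exp(beta + stats::qnorm(0.975) * se)
    pv <- sm["in_set", "Pr(>|z|)"]
  }
  tibble::tibble(method = if (covariate_used) "logistic_covariate" else
                   "logistic", odds_ratio = or, conf.low = lo, conf.high = hi,
                 p.value = pv, A = A, B = B, C = C, D = D,
                 n = nrow(annotation), separated = separated)
}

#' BH adjustment over a (class x set) enrichment grid
#'
#' Adjusts raw p-values across every tested cell of the element-class by
#' curated-gene-set grid in a single family.
#'
#' @param grid Tibble with columns `class`, `set`, `p.value` (NA for
#'   untested cells).
#' @param method Adjustment method passed to [stats::p.adjust()]
#'   (default "BH").
#' @return `grid` with added `q`; attribute `family_size` gives the number
#'   of non-NA cells.
#' @export
correct_grid <- function(grid, method = "BH") {
  grid <- tibble::as_tibble(grid)
  stopifnot(all(c("class", "set", "p.value") %in% names(grid)))
  tested <- !is.na(grid$p.value)
  grid$q <- NA_real_
  grid$q[tested] <- stats::p.adjust(grid$p.value[tested], method = method)
  attr(grid, "family_size") <- sum(tested)
  attr(grid, "method") <- method
  grid
}
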