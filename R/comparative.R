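#' Per-gene stage Z-scores
#'
#' Standardizes each gene's expression across developmental stages
#' ((x - row mean) / row SD), so the Z-score measures relative enrichment
#' of a gene at a stage compared with its other stages. Genes constant
#' across stages cannot be standardized and are dropped (recorded in the
#' `dropped` attribute).
#'
#' @param expr Expression tibble (`gene_id` + one column per stage; at
#'   least 3 stages).
#' @return Z-score tibble of the same shape, with attribute `dropped`
#'   listing excluded constant genes.
#' @export
stage_zscores <- function(expr) {
  m <- expr_matrix(expr)
  if (ncol(m) < 3) stop("need at least 3 stages")
  sds <- apply(m, 1, stats::sd)
  dropped <- rownames(m)[sds == 0]
  m <- m[sds > 0, , drop = FALSE]
  z <- (m - rowMeans(m)) / sds[sds > 0]
  out <- matrix_to_expr(z)
  attr(out, "dropped") <- dropped
  out
}

#' Cross-species expression Z-score differences at matched stages
#'
#' For every ortholog present in both Z-score matrices and every matched
#' stage pair, computes `delta = Z_human(stage_h) - Z_other(stage_o)`.
#' Positive values mean the gene is relatively more stage-enriched in
#' human. The gene-set effect is tested by a two-sided two-sample t-test
#' of the pooled set deltas against the pooled background deltas
#' (non-set orthologs by default).
#'
#' @param human_z,other_z Z-score tibbles from [stage_zscores()]; stage
#'   pairs refer to their column names.
#' @param pairs Tibble of matched stages with columns `human_stage`,
#'   `other_stage` (and optionally the event scores `human_score`,
#'   `other_score`).
#' @param gene_set Character vector of gene ids.
#' @param background Optional character vector; defaults to all shared
#'   orthologs not in `gene_set`.
#' @return A `delta_z_result`: list with `deltas` (long tibble `gene_id`,
#'   `human_stage`, `other_stage`, `delta`, `in_set`), `mean_delta`
#'   (gene-set mean), `statistic`, `p.value`, counts.
#' @export
delta_z <- function(human_z, other_z, pairs, gene_set, background = NULL) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(nrow(pairs) >= 1,
            all(c("human_stage", "other_stage") %in% names(pairs)))
  mh <- expr_matrix(human_z)
  mo <- expr_matrix(other_z)
  stopifnot(all(pairs$human_stage %in% colnames(mh)),
            all(pairs$other_stage %in% colnames(mo)))
  shared <- intersect(rownames(mh), rownames(mo))
  n_excluded <- length(union(rownames(mh), rownames(mo))) - length(shared)
  deltas <- purrr::pmap(pairs[c("human_stage", "other_stage")],
                        function(human_stage, other_stage) {
    d <- unname(mh[shared, human_stage] - mo[shared, other_stage])
    tibble::tibble(gene_id = shared,
                   human_stage = human_stage, other_stage = other_stage,
                   delta = d)
  }) |> dplyr::bind_rows()
  if (is.null(background)) background <- setdiff(shared, gene_set)
  deltas$in_set <- deltas$gene_id %in% gene_set
  set_d <- deltas$delta[deltas$in_set]
  bg_d <- deltas$delta[deltas$gene_id %in% background & !deltas$in_set]
  if (length(set_d) < 2 || length(bg_d) < 2) {
    stop("need at least 2 delta observations in both set and background")
  }
  if (stats::sd(set_d) == 0 && stats::sd(bg_d) == 0) {
    # degenerate but well-defined: no variance anywhere means no evidence
    tt <- list(statistic = c(t = 0),
               p.value = if (mean(set_d) == mean(bg_d)) 1 else 0)
  } else {
    tt <- stats::t.test(set_d, bg_d)
  }
  structure(list(deltas = deltas,
                 mean_delta = mean(set_d) - mean(bg_d),
                 mean_set = mean(set_d), mean_background = mean(bg_d),
                 statistic = unname(tt$statistic), p.value = tt$p.value,
                 n_set = sum(deltas$in_set), n_background = length(bg_d),
                 n_excluded = n_excluded),
            class = "delta_z_result")
}

#' @export
print.delta_z_result <- function(x, ...) {
  cat(sprintf(paste0("Delta expression Z: set mean = %.4f vs background ",
                     "%.4f (delta = %.4f)\n  t = %.3f, p = %.3g ",
                     "(%d set / %d background observations)\n"),
              x$mean_set, x$mean_background, x$mean_delta, x$statistic,
              x$p.value, x$n_set, x$n_background))
  invisible(x)
}

#' @method tidy delta_z_result
#' @export
tidy.delta_z_result <- function(x, ...) x$deltas

#' @method glance delta_z_result
#' @export
glance.delta_z_result <- function(x, ...) {
  tibble::tibble(mean_delta = x$mean_delta, mean_set = x$mean_set,
                 mean_background = x$mean_background,
                 statistic = x$statistic, p.value = x$p.value,
                 n_set = x$n_set, n_background = x$n_background)
}

#' Breakpoint-shift test between a gene set and background
#'
#' Compares per-gene breakpoint differences (human minus rhesus, in
#' event-score units; negative = earlier in human) between a gene set and
#' a disjoint background by a two-sided Wilcoxon rank-sum test.
#'
#' @param table Tibble with columns `gene_id`, `delta`.
#' @param gene_set,background Disjoint character vectors of gene ids (both
#'   with at least 5 genes present in `table`).
#' @return One-row tibble: medians, `median_diff`, `p.value`, `direction`
#'   (`earlier_in_human` / `later_in_human` / `none`).
#' @export
breakpoint_shift <- function(table, gene_set, background) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("gene_id", "delta") %in% names(table)))
  if (length(intersect(gene_set, background)) > 0) {
    stop("background must exclude the gene set")
  }
  x <- table$delta[table$gene_id %in% gene_set]
  y <- table$delta[table$gene_id %in% background]
  if (length(x) < 5 || length(y) < 5) stop("both groups need >= 5 genes")
  wt <- stats::wilcox.test(x, y)
  md <- stats::median(x) - stats::median(y)
  tibble::tibble(median_set = stats::median(x),
                 median_background = stats::median(y),
                 median_diff = md, p.value = wt$p.value,
                 n_set = length(x), n_background = length(y),
                 direction = dplyr::case_when(md < 0 ~ "earlier_in_human",
                                              md > 0 ~ "later_in_human",
                                              TRUE ~ "none"))
}

#' Selection-pressure contrast via log2(dN/dS)
#'
#' Computes `log2(dN/dS)` per gene (dS = 0 records excluded with a count)
#' and compares a gene set with a background by a two-sided Wilcoxon
#' rank-sum test. A gene-set median below 0 is called purifying selection.
#'
#' @param records Tibble with columns `gene_id`, `dN`, `dS` (optionally
#'   `species_pair`, in which case one result row per pair is returned).
#' @param gene_set,background Character vectors of gene ids.
#' @return Tibble with medians, `p.value`, `purifying` flag and
#'   `n_excluded` (dS = 0 records).
#' @export
dnds_contrast <- function(records, gene_set, background) {
  records <- tibble::as_tibble(records)
  stopifnot(all(c("gene_id", "dN", "dS") %in% names(records)))
  if (any(records$dN < 0 | records$dS < 0)) stop("negative dN or dS")
  if (!"species_pair" %in% names(records)) records$species_pair <- "all"
  records |>
    dplyr::group_by(.data$species_pair) |>
    dplyr::group_modify(function(d, key) {
      n_excluded <- sum(d$dS == 0)
      d <- d[d$dS > 0, ]
      lr <- log2(d$dN / d$dS)
      x <- lr[d$gene_id %in% gene_set]
      y <- lr[d$gene_id %in% background & !d$gene_id %in% gene_set]
      if (length(x) < 2 || length(y) < 2) stop("too few genes for contrast")
      wt <- stats::wilcox.test(x, y)
      tibble::tibble(median_set = stats::median(x),
                     median_background = stats::median(y),
                     p.value = wt$p.value,
                     purifying = stats::median(x) < 0,
                     n_set = length(x), n_background = length(y),
                     n_excluded = n_excluded)
    }) |>
    dplyr::ungroup()
}

#' Co-expression module membership enrichment
#'
#' For each module, builds the 2x2 table of (in gene set) x (in module)
#' over the declared background and reports the sample odds ratio with
#' Fisher's exact p-value (the covariate-free logistic model is equivalent),
#' BH-adjusted across modules.
#'
#' @param gene_set Character vector (must be a subset of `background`).
#' @param modules Tibble with columns `gene_id`, `module`.
#' @param background Character vector of all genes in the co-expression
#'   analysis. Modules with no gene in the background are skipped.
#' @return Tibble with one row per module: counts, `odds_ratio`, CI,
#'   `p.value`, `q`.
#' @export
module_enrichment <- function(gene_set, modules, background) {
  modules <- tibble::as_tibble(modules)
  stopifnot(all(c("gene_id", "module") %in% names(modules)))
  if (!all(gene_set %in% background)) {
    stop("gene_set must be contained in background")
  }
  in_set <- background %in% gene_set
  rows <- modules |>
    dplyr::group_by(.data$module) |>
    dplyr::group_modify(function(d, key) {
      in_mod <- background %in% d$gene_id
      if (!any(in_mod)) return(tibble::tibble())
      A <- sum(in_set & in_mod); B <- sum(!in_set & in_mod)
      C <- sum(in_set & !in_mod); D <- sum(!in_set & !in_mod)
      ci <- or_with_ci(A, B, C, D)
      pv <- stats::fisher.test(matrix(c(A, B, C, D), 2, byrow = TRUE))$p.value
      tibble::tibble(A = A, B = B, C = C, D = D,
                     odds_ratio = ci$odds_ratio, conf.low = ci$conf.low,
                     conf.high = ci$conf.high, p.value = pv)
    }) |>
    dplyr::ungroup()
  rows$q <- stats::p.adjust(rows$p.value, method = "BH")
  dplyr::arrange(rows, .data$q, .data$p.value)
}
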