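# Expression tables are tibbles whose first column is `gene_id` and whose
# remaining columns are samples (or cells / stages). Convert to a matrix.
expr_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), names(expr)[1] == "gene_id")
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$gene_id
  storage.mode(m) <- "double"
  m
}

matrix_to_expr <- function(m) {
  out <- tibble::as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble::tibble(gene_id = rownames(m)), out)
}

#' Center expression to each sample's mean
#'
#' The bulk-atlas convention: values are (optionally) log2(x + 1)
#' transformed, then each sample (column) is centered to its mean and
#' offset by +1, so a value of 1 means "at the sample average". Column
#' means of the centered values are exactly 1.
#'
#' @param expr Expression tibble (`gene_id` + one column per sample).
#' @param log_transform Apply log2(x + 1) first (requires non-negative
#'   input).
#' @return Centered expression tibble of the same shape.
#' @export
center_by_sample <- function(expr, log_transform = TRUE) {
  m <- expr_matrix(expr)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty expression matrix")
  if (log_transform) {
    if (any(m < 0)) stop("log transform requires non-negative values")
    m <- log2(m + 1)
  }
  centered <- sweep(m, 2, colMeans(m)) + 1
  matrix_to_expr(centered)
}

#' Developmental trajectories of gene sets with period comparisons
#'
#' Computes the per-sample mean centered expression of each gene set, then
#' compares element classes within each period (prenatal/postnatal) by
#' one-way ANOVA with post-hoc Tukey contrasts; Tukey p-values are
#' BH-adjusted across all contrasts of all periods.
#'
#' @param centered Centered expression tibble from [center_by_sample()].
#' @param metadata Sample metadata tibble with columns `sample`, `period`
#'   (and optionally `stage`, `age`).
#' @param gene_sets Named list of gene-id vectors (one per element class).
#' @return A `trajectory_result`: list with `trajectory` (tibble of
#'   `sample`, `class`, `mean_expr`, metadata columns) and `contrasts`
#'   (Tukey contrasts with `p.value` and BH `q`).
#' @export
group_trajectory <- function(centered, metadata, gene_sets) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  m <- expr_matrix(centered)
  metadata <- tibble::as_tibble(metadata)
  stopifnot(all(c("sample", "period") %in% names(metadata)),
            all(colnames(m) %in% metadata$sample))
  traj <- purrr::imap(gene_sets, function(genes, cls) {
    present <- intersect(genes, rownames(m))
    if (length(present) < 2) {
      stop("gene set '", cls, "' has fewer than 2 genes in the matrix")
    }
    tibble::tibble(sample = colnames(m), class = cls,
                   mean_expr = unname(colMeans(m[present, , drop = FALSE])))
  }) |>
    dplyr::bind_rows() |>
    dplyr::left_join(metadata, by = "sample")
  contrasts <- traj |>
    dplyr::group_by(.data$period) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$class)) < 2) return(tibble::tibble())
      fit <- stats::aov(mean_expr ~ class, data = d)
      tk <- stats::TukeyHSD(fit)$class
      tibble::tibble(contrast = rownames(tk), diff = tk[, "diff"],
                     conf.low = tk[, "lwr"], conf.high = tk[, "upr"],
                     p.value = tk[, "p adj"],
                     anova_p = summary(fit)[[1]][["Pr(>F)"]][1])
    }) |>
    dplyr::ungroup()
  contrasts$q <- stats::p.adjust(contrasts$p.value, method = "BH")
  structure(list(trajectory = traj, contrasts = contrasts),
            class = "trajectory_result")
}

#' @export
print.trajectory_result <- function(x, ...) {
  cat("Gene-set trajectories:", length(unique(x$trajectory$class)),
      "classes x", length(unique(x$trajectory$sample)), "samples\n")
  cat("Contrasts (BH-adjusted):\n")
  print(x$contrasts, ...)
  invisible(x)
}

#' @method tidy trajectory_result
#' @export
tidy.trajectory_result <- function(x, ...) x$contrasts

#' @method glance trajectory_result
#' @export
glance.trajectory_result <- function(x, ...) {
  tibble::tibble(n_classes = length(unique(x$trajectory$class)),
                 n_samples = length(unique(x$trajectory$sample)),
                 n_contrasts = nrow(x$contrasts),
                 min_q = suppressWarnings(min(x$contrasts$q)))
}

#' Cell-type profile of a gene set
#'
#' Single-cell convention: each cell (column) is centered to its own mean
#' (no +1 offset), the centered values of the gene set are averaged per
#' cell, and cell averages are averaged within each cluster.
#'
#' @param cells Expression tibble (`gene_id` + one column per cell).
#' @param clusters Tibble with columns `cell`, `cluster` labelling every
#'   cell.
#' @param gene_set Character vector of gene ids (non-empty in the matrix).
#' @return Tibble with `cluster`, `n_cells`, `mean_centered`.
#' @export
celltype_profile <- function(cells, clusters, gene_set) {
  m <- expr_matrix(cells)
  clusters <- tibble::as_tibble(clusters)
  stopifnot(all(c("cell", "cluster") %in% names(clusters)))
  present <- intersect(gene_set, rownames(m))
  if (length(present) == 0) stop("gene set absent from the matrix")
  centered <- sweep(m, 2, colMeans(m))
  per_cell <- colMeans(centered[present, , drop = FALSE])
  known <- clusters$cell %in% names(per_cell)
  empty <- setdiff(unique(clusters$cluster), unique(clusters$cluster[known]))
  if (length(empty) > 0) {
    warning("cluster(s) with no cells in the matrix excluded: ",
            paste(empty, collapse = ", "))
  }
  tibble::tibble(cell = names(per_cell), value = per_cell) |>
    dplyr::left_join(clusters, by = "cell") |>
    dplyr::filter(!is.na(.data$cluster)) |>
    dplyr::summarise(n_cells = dplyr::n(),
                     mean_centered = mean(.data$value), .by = "cluster") |>
    dplyr::arrange(.data$cluster)
}
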