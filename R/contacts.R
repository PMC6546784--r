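#' Build a binned intra-chromosomal contact matrix
#'
#' Stores sparse upper-triangular 10 kb-binned contacts per chromosome.
#' Bin indices are 0-based: bin `b` covers `[b * bin_size, (b+1) * bin_size)`.
#'
#' @param triplets Tibble with columns `chrom`, `bin1`, `bin2`, `count`
#'   (COO triplets; `bin1`/`bin2` in either order, counts non-negative).
#' @param bin_size Bin width in bp (default 10000).
#' @param chrom_sizes Named chromosome lengths in bp.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(triplets, bin_size = 10000, chrom_sizes = NULL) {
  stopifnot(all(c("chrom", "bin1", "bin2", "count") %in% names(triplets)),
            bin_size > 0)
  triplets <- tibble::as_tibble(triplets)
  if (any(triplets$count < 0)) stop("negative contact values")
  i <- pmin(triplets$bin1, triplets$bin2)
  j <- pmax(triplets$bin1, triplets$bin2)
  triplets$bin1 <- i; triplets$bin2 <- j
  if (any(i < 0)) stop("negative bin index")
  sizes <- if (is.null(chrom_sizes)) NULL else as_chrom_sizes(chrom_sizes)
  chroms <- unique(triplets$chrom)
  n_bins <- vapply(chroms, function(chr) {
    sub_max <- max(triplets$bin2[triplets$chrom == chr]) + 1
    if (!is.null(sizes)) {
      nb <- ceiling(sizes[[chr]] / bin_size)
      if (sub_max > nb) stop("bin index beyond chromosome end on ", chr)
      nb
    } else sub_max
  }, numeric(1))
  names(n_bins) <- chroms
  mats <- lapply(chroms, function(chr) {
    sub <- triplets[triplets$chrom == chr, ]
    Matrix::sparseMatrix(i = sub$bin1 + 1, j = sub$bin2 + 1, x = sub$count,
                         dims = c(n_bins[[chr]], n_bins[[chr]]))
  })
  names(mats) <- chroms
  structure(list(mats = mats, bin_size = bin_size, n_bins = n_bins),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("Contact matrix:", length(x$mats), "chromosome(s), bin size",
      x$bin_size, "bp\n")
  for (chr in names(x$mats)) {
    cat(sprintf("  %s: %d bins, %d non-zero contacts\n", chr,
                x$n_bins[[chr]], Matrix::nnzero(x$mats[[chr]])))
  }
  invisible(x)
}

#' @method tidy contact_matrix
#' @export
tidy.contact_matrix <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$mats), function(chr) {
    tm <- Matrix::summary(x$mats[[chr]])
    tibble::tibble(chrom = chr, bin1 = tm$i - 1, bin2 = tm$j - 1, count = tm$x)
  }))
}

#' Read contacts from COO text
#'
#' Expects a tab-separated file with header `chrom, bin1, bin2, count`.
#'
#' @param path Input path.
#' @inheritParams contact_matrix
#' @return A `contact_matrix`.
#' @export
read_contacts <- function(path, bin_size = 10000, chrom_sizes = NULL) {
  df <- readr::read_tsv(path, col_types = "cddd", progress = FALSE)
  contact_matrix(df, bin_size = bin_size, chrom_sizes = chrom_sizes)
}

#' Write contacts as COO text
#' @param cm A `contact_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(cm, path) {
  readr::write_tsv(tidy(cm), path)
  invisible(path)
}

#' Anchor bins intersected by elements
#'
#' Every bin touched by the element becomes an anchor; elements straddling
#' a bin boundary therefore yield one locus per touched bin.
#'
#' @param elements Interval tibble.
#' @param bin_size Bin width in bp.
#' @return Tibble with `element`, `chrom`, `anchor` (0-based bin index).
#' @export
bin_anchors <- function(elements, bin_size = 10000) {
  stopifnot(bin_size > 0)
  elements <- as_intervals(elements)
  ids <- if ("name" %in% names(elements)) elements$name else
    paste0("el", seq_len(nrow(elements)))
  first <- floor(elements$start / bin_size)
  last <- floor((elements$end - 1) / bin_size)
  tibble::tibble(element = ids, chrom = elements$chrom,
                 first = first, last = last) |>
    dplyr::rowwise() |>
    dplyr::reframe(element = .data$element, chrom = .data$chrom,
                   anchor = seq(.data$first, .data$last))
}

# Offsets tested around an anchor: +-1..+-(window/bin_size - 1), i.e. the
# bins strictly within the flanking window (198 candidates for a 1 Mb
# window at 10 kb resolution).
candidate_offsets <- function(window, bin_size) {
  k <- floor(window / bin_size) - 1
  c(-k:-1, 1:k)
}

#' Contact profiles of anchor loci
#'
#' For each anchor bin, extracts the contact value to every candidate bin
#' within the flanking window (offsets excluding the anchor itself, clipped
#' at chromosome ends; absent matrix entries read as 0).
#'
#' @param cm A `contact_matrix`.
#' @param anchors Tibble with `element`, `chrom`, `anchor` (from
#'   [bin_anchors()]), or any tibble with `chrom` + `anchor`.
#' @param window Flanking window in bp (default 1e6, giving 198 candidates
#'   per interior anchor at 10 kb bins).
#' @return Tibble with `element`, `chrom`, `anchor`, `candidate`, `offset`,
#'   `distance`, `contact`.
#' @export
locus_profiles <- function(cm, anchors, window = 1e6) {
  stopifnot(inherits(cm, "contact_matrix"))
  anchors <- tibble::as_tibble(anchors)
  if (!"element" %in% names(anchors)) {
    anchors$element <- paste0("anchor", seq_len(nrow(anchors)))
  }
  offsets <- candidate_offsets(window, cm$bin_size)
  out <- vector("list", length(cm$mats))
  for (chr in unique(anchors$chrom)) {
    if (!chr %in% names(cm$mats)) stop("no contacts for chromosome ", chr)
    sub <- anchors[anchors$chrom == chr, ]
    nb <- cm$n_bins[[chr]]
    if (any(sub$anchor < 0 | sub$anchor >= nb)) {
      stop("anchor outside chromosome ", chr)
    }
    mat <- cm$mats[[chr]]
    pieces <- lapply(offsets, function(off) {
      cand <- sub$anchor + off
      keep <- cand >= 0 & cand < nb
      if (!any(keep)) return(NULL)
      a <- sub$anchor[keep]; cd <- cand[keep]
      val <- mat[cbind(pmin(a, cd) + 1, pmax(a, cd) + 1)]
      tibble::tibble(element = sub$element[keep], chrom = chr, anchor = a,
                     candidate = cd, offset = off,
                     distance = abs(off) * cm$bin_size, contact = as.numeric(val))
    })
    out[[chr]] <- dplyr::bind_rows(pieces)
  }
  dplyr::bind_rows(out) |>
    dplyr::arrange(.data$element, .data$anchor, .data$offset)
}

#' @rdname locus_profiles
#' @param chrom,anchor Chromosome and 0-based anchor bin for a single locus.
#' @export
locus_profile <- function(cm, chrom, anchor, window = 1e6) {
  locus_profiles(cm, tibble::tibble(element = "locus", chrom = chrom,
                                    anchor = anchor), window = window)
}
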