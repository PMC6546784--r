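#' Assign elements to putative target genes
#'
#' Combines direct (coordinate-based) assignment with interaction-based
#' assignment from significant contact calls whose candidate bin overlaps a
#' gene promoter (2 kb upstream of the TSS by default). Three modes mirror
#' the three element classes' conventions:
#'
#' * `fetal_full`: elements classified as coding (exon/UTR/1 kb
#'   promoter/downstream flank) are assigned directly to their owning
#'   genes; interaction targets are added for noncoding elements only.
#' * `promoter_split`: elements overlapping a 2 kb promoter are assigned
#'   directly to that promoter's gene; all other elements get interaction
#'   targets.
#' * `adult_promoter_only`: no direct assignment; only interaction calls
#'   landing in promoters are used, for all elements.
#'
#' @param calls Corrected call tibble from [correct_and_call()] (columns
#'   `element`, `chrom`, `candidate`, `q`, `significant`).
#' @param elements Interval tibble with a `name` column matching
#'   `calls$element`.
#' @param genes A `gene_model` tibble.
#' @param mode Assignment mode (see above).
#' @param bin_size Contact bin width in bp.
#' @param promoter_bp Promoter width for target mapping (default 2000).
#' @param chrom_sizes Optional chromosome sizes for clipping.
#' @return Tibble with `element`, `gene_id`, `evidence`
#'   (`coding_direct` or `interaction`) and `q` (NA for direct
#'   assignments; minimum q over supporting calls otherwise).
#' @export
assign_targets <- function(calls, elements, genes,
                           mode = c("fetal_full", "promoter_split",
                                    "adult_promoter_only"),
                           bin_size = 10000, promoter_bp = 2000,
                           chrom_sizes = NULL) {
  mode <- match.arg(mode)
  elements <- as_intervals(elements)
  if (!"name" %in% names(elements)) {
    elements$name <- paste0("el", seq_len(nrow(elements)))
  }
  promoters <- promoter_regions(genes, promoter_bp, chrom_sizes)

  direct <- tibble::tibble(element = character(0), gene_id = character(0))
  interaction_elements <- elements$name
  if (mode == "fetal_full") {
    cls <- classify_elements(elements, genes, chrom_sizes)
    coding <- cls[cls$coding, ]
    direct <- tidyr::unnest(
      tibble::tibble(element = coding$name, gene_id = coding$gene_ids),
      "gene_id")
    interaction_elements <- cls$name[!cls$coding]
  } else if (mode == "promoter_split") {
    hits <- overlap_pairs(elements, promoters)
    direct <- tibble::tibble(element = elements$name[hits$a_index],
                             gene_id = promoters$name[hits$b_index]) |>
      dplyr::distinct()
    interaction_elements <- setdiff(elements$name, direct$element)
  }

  sig <- calls[calls$significant & calls$element %in% interaction_elements, ]
  inter <- tibble::tibble(element = character(0), gene_id = character(0),
                          q = numeric(0))
  if (nrow(sig) > 0) {
    cand <- tibble::tibble(chrom = sig$chrom,
                           start = sig$candidate * bin_size,
                           end = (sig$candidate + 1) * bin_size)
    gr_c <- intervals_to_granges(cand)
    gr_p <- intervals_to_granges(promoters)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_c, gr_p))
    if (length(hits) > 0) {
      inter <- tibble::tibble(
        element = sig$element[S4Vectors::queryHits(hits)],
        gene_id = promoters$name[S4Vectors::subjectHits(hits)],
        q = sig$q[S4Vectors::queryHits(hits)]
      ) |>
        dplyr::summarise(q = min(.data$q), .by = c("element", "gene_id"))
    }
  }

  out <- dplyr::bind_rows(
    dplyr::mutate(dplyr::distinct(direct), evidence = "coding_direct",
                  q = NA_real_),
    dplyr::mutate(inter, evidence = "interaction")
  )
  # direct evidence wins when both routes nominate the same (element, gene)
  out |>
    dplyr::arrange(.data$element, .data$gene_id,
                   .data$evidence != "coding_direct") |>
    dplyr::distinct(.data$element, .data$gene_id, .keep_all = TRUE) |>
    dplyr::select("element", "gene_id", "evidence", "q")
}
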