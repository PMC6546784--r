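#' Construct a gene-model table
#'
#' One row per gene with a single representative transcript structure.
#' Coordinates follow the package-wide 0-based half-open convention; the
#' TSS is the 5' end with respect to strand (`start` for `+`, `end` for
#' `-`), and `cds_length` (total coding-exon bp) carries the coding-length
#' covariate used by [logistic_enrichment()].
#'
#' @param gene_id Character vector of gene identifiers.
#' @param chrom,strand,start,end Gene body coordinates and strand (`+`/`-`).
#' @param exons,cds,utr5,utr3 Optional lists of interval tibbles
#'   (`start`, `end`), one element per gene. When `exons` is omitted the
#'   gene body is used as a single exon.
#' @return A `gene_model` tibble with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `tss`, `tes`, `cds_length` and list-columns `exons`,
#'   `cds`, `utr5`, `utr3`.
#' @export
gene_models <- function(gene_id, chrom, strand, start, end,
                        exons = NULL, cds = NULL, utr5 = NULL, utr3 = NULL) {
  n <- length(gene_id)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(strand) == 1) strand <- rep(strand, n)
  stopifnot(length(chrom) == n, length(strand) == n,
            all(strand %in% c("+", "-")), all(start < end))
  empty <- tibble::tibble(start = numeric(0), end = numeric(0))
  fill <- function(lst) {
    if (is.null(lst)) rep(list(empty), n) else lapply(lst, tibble::as_tibble)
  }
  if (is.null(exons)) {
    exons <- purrr::map2(start, end, ~ tibble::tibble(start = .x, end = .y))
  } else {
    exons <- lapply(exons, function(e) dplyr::arrange(tibble::as_tibble(e), start))
  }
  cds <- fill(cds)
  out <- tibble::tibble(
    gene_id = unname(as.character(gene_id)),
    chrom = unname(as.character(chrom)),
    strand = unname(strand),
    start = unname(as.numeric(start)),
    end = unname(as.numeric(end)),
    tss = ifelse(strand == "+", as.numeric(start), as.numeric(end)),
    tes = ifelse(strand == "+", as.numeric(end), as.numeric(start)),
    cds_length = unname(vapply(cds, function(x) sum(x$end - x$start),
                               numeric(1))),
    exons = unname(exons),
    cds = unname(cds),
    utr5 = unname(fill(utr5)),
    utr3 = unname(fill(utr3))
  )
  class(out) <- c("gene_model", class(out))
  out
}

#' Read gene models from a GTF subset
#'
#' Parses `gene`, `exon` and `CDS` lines of a GTF file (1-based closed
#' coordinates, converted to 0-based half-open on read). Exons and CDS of
#' all transcripts are pooled per gene; the representative TSS is the
#' 5'-most position. UTRs are derived as exonic sequence outside the CDS
#' span, split into 5' and 3' by strand.
#'
#' @param path Path to a tab-separated GTF file.
#' @return A `gene_model` tibble (see [gene_models()]).
#' @export
read_gtf_genes <- function(path) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9)) stop("malformed GTF line ", which(lengths(f) < 9)[1])
  feat <- vapply(f, `[[`, "", 3L)
  keep <- feat %in% c("gene", "exon", "CDS")
  f <- f[keep]; feat <- feat[keep]
  gid <- stringr::str_match(vapply(f, `[[`, "", 9L),
                            'gene_id "([^"]+)"')[, 2]
  if (anyNA(gid)) stop("GTF line without gene_id attribute")
  df <- tibble::tibble(
    chrom = vapply(f, `[[`, "", 1L),
    feature = feat,
    start = as.numeric(vapply(f, `[[`, "", 4L)) - 1,  # GTF -> 0-based
    end = as.numeric(vapply(f, `[[`, "", 5L)),
    strand = vapply(f, `[[`, "", 7L),
    gene_id = gid
  )
  per_gene <- split(df, df$gene_id)
  rows <- lapply(per_gene, function(g) {
    body_start <- min(g$start); body_end <- max(g$end)
    strand <- g$strand[1]
    ex <- g[g$feature == "exon", c("start", "end")]
    if (nrow(ex) == 0) ex <- tibble::tibble(start = body_start, end = body_end)
    ex <- collapse_intervals(ex)
    cd <- collapse_intervals(g[g$feature == "CDS", c("start", "end")])
    utr <- derive_utrs(ex, cd, strand)
    list(gene_id = g$gene_id[1], chrom = g$chrom[1], strand = strand,
         start = body_start, end = body_end,
         exons = ex, cds = cd, utr5 = utr$utr5, utr3 = utr$utr3)
  })
  gene_models(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    strand = vapply(rows, `[[`, "", "strand"),
    start = vapply(rows, `[[`, numeric(1), "start"),
    end = vapply(rows, `[[`, numeric(1), "end"),
    exons = lapply(rows, `[[`, "exons"),
    cds = lapply(rows, `[[`, "cds"),
    utr5 = lapply(rows, `[[`, "utr5"),
    utr3 = lapply(rows, `[[`, "utr3")
  )
}

# Merge overlapping/adjacent (start, end) rows into disjoint sorted runs.
collapse_intervals <- function(df) {
  if (nrow(df) == 0) return(tibble::tibble(start = numeric(0), end = numeric(0)))
  df <- df[order(df$start, df$end), ]
  out_s <- df$start[1]; out_e <- df$end[1]
  if (nrow(df) > 1) {
    for (i in 2:nrow(df)) {
      k <- length(out_s)
      if (df$start[i] <= out_e[k]) {
        out_e[k] <- max(out_e[k], df$end[i])
      } else {
        out_s <- c(out_s, df$start[i]); out_e <- c(out_e, df$end[i])
      }
    }
  }
  tibble::tibble(start = out_s, end = out_e)
}

# Exonic sequence outside the CDS span, labelled 5'/3' by strand.
derive_utrs <- function(exons, cds, strand) {
  empty <- tibble::tibble(start = numeric(0), end = numeric(0))
  if (nrow(cds) == 0) return(list(utr5 = empty, utr3 = empty))
  cs <- min(cds$start); ce <- max(cds$end)
  left <- clip_intervals(exons, -Inf, cs)
  right <- clip_intervals(exons, ce, Inf)
  if (strand == "+") list(utr5 = left, utr3 = right)
  else list(utr5 = right, utr3 = left)
}

clip_intervals <- function(df, lo, hi) {
  s <- pmax(df$start, lo); e <- pmin(df$end, hi)
  keep <- s < e
  tibble::tibble(start = s[keep], end = e[keep])
}

#' Write gene models as a GTF subset
#'
#' Emits `gene`, `exon` and `CDS` lines (converting back to GTF 1-based
#' closed coordinates) so that [read_gtf_genes()] round-trips.
#'
#' @param genes A `gene_model` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf_genes <- function(genes, path) {
  lines <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    attr9 <- sprintf('gene_id "%s";', g$gene_id)
    mk <- function(feature, s, e) {
      sprintf("%s\tevotarget\t%s\t%d\t%d\t.\t%s\t.\t%s",
              g$chrom, feature, as.integer(s) + 1L, as.integer(e), g$strand, attr9)
    }
    lines <- c(lines, mk("gene", g$start, g$end))
    ex <- g$exons[[1]]
    lines <- c(lines, mapply(mk, "exon", ex$start, ex$end))
    cd <- g$cds[[1]]
    if (nrow(cd) > 0) lines <- c(lines, mapply(mk, "CDS", cd$start, cd$end))
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Promoter intervals upstream of each TSS
#'
#' For `+` strand genes the promoter is `[tss - upstream_bp, tss)`; for `-`
#' strand genes `[tss, tss + upstream_bp)`. Intervals are clipped to
#' chromosome bounds when sizes are supplied.
#'
#' @param genes A `gene_model` tibble.
#' @param upstream_bp Promoter width in bp (default 2000, the width used
#'   for interaction target mapping; element classification uses 1000).
#' @param chrom_sizes Optional chromosome sizes for clipping.
#' @return Interval tibble with `name` = `gene_id`.
#' @export
promoter_regions <- function(genes, upstream_bp = 2000, chrom_sizes = NULL) {
  stopifnot(upstream_bp > 0)
  s <- ifelse(genes$strand == "+", genes$tss - upstream_bp, genes$tss)
  e <- ifelse(genes$strand == "+", genes$tss, genes$tss + upstream_bp)
  s <- pmax(s, 0)
  if (!is.null(chrom_sizes)) {
    sizes <- as_chrom_sizes(chrom_sizes)
    e <- pmin(e, sizes[genes$chrom])
  }
  keep <- s < e
  as_intervals(tibble::tibble(chrom = genes$chrom[keep], start = s[keep],
                              end = e[keep], name = genes$gene_id[keep]))
}

# Downstream flanks (after the TES, strand-aware), clipped likewise.
downstream_regions <- function(genes, downstream_bp = 1000, chrom_sizes = NULL) {
  s <- ifelse(genes$strand == "+", genes$tes, genes$tes - downstream_bp)
  e <- ifelse(genes$strand == "+", genes$tes + downstream_bp, genes$tes)
  s <- pmax(s, 0)
  if (!is.null(chrom_sizes)) {
    sizes <- as_chrom_sizes(chrom_sizes)
    e <- pmin(e, sizes[genes$chrom])
  }
  keep <- s < e
  as_intervals(tibble::tibble(chrom = genes$chrom[keep], start = s[keep],
                              end = e[keep], name = genes$gene_id[keep]))
}

#' Classify elements against gene models
#'
#' Assigns each element one of the categories `exon`, `utr5`, `utr3`,
#' `promoter1kb`, `downstream1kb`, `intron`, `intergenic` using the fixed
#' precedence exon > utr5 > utr3 > promoter1kb > downstream1kb > intron >
#' intergenic when an element overlaps several features. The `exon`
#' category means coding exon sequence (CDS) for coding genes and any exon
#' for genes without a CDS. Elements in any of the first five categories
#' are flagged `coding` and carry the owning gene id(s); an element
#' touching coding-category features of several genes is assigned to all
#' of them.
#'
#' @param elements Interval tibble of elements.
#' @param genes A `gene_model` tibble.
#' @param chrom_sizes Optional chromosome sizes for promoter/flank clipping.
#' @param promoter_bp,downstream_bp Widths of the promoter and downstream
#'   flank categories (both 1000 bp, the classification convention; distinct
#'   from the 2 kb promoters used for target mapping).
#' @return The element tibble with added `category`, `coding` and list
#'   column `gene_ids`.
#' @export
classify_elements <- function(elements, genes, chrom_sizes = NULL,
                              promoter_bp = 1000, downstream_bp = 1000) {
  elements <- as_intervals(elements)
  feats <- list(
    exon = gene_feature_intervals(genes, function(g) {
      if (nrow(g$cds[[1]]) > 0) g$cds[[1]] else g$exons[[1]]
    }),
    utr5 = gene_feature_intervals(genes, function(g) g$utr5[[1]]),
    utr3 = gene_feature_intervals(genes, function(g) g$utr3[[1]]),
    promoter1kb = promoter_regions(genes, promoter_bp, chrom_sizes),
    downstream1kb = downstream_regions(genes, downstream_bp, chrom_sizes),
    intron = gene_feature_intervals(genes, function(g) {
      gaps_within(g$exons[[1]], g$start, g$end)
    })
  )
  n <- nrow(elements)
  category <- rep("intergenic", n)
  hit_genes <- replicate(n, character(0), simplify = FALSE)
  coding_cats <- c("exon", "utr5", "utr3", "promoter1kb", "downstream1kb")
  for (cat in rev(names(feats))) {  # lowest precedence first, overwritten later
    fs <- feats[[cat]]
    if (nrow(fs) == 0) next
    hits <- overlap_pairs(elements, fs)
    if (nrow(hits) > 0) category[unique(hits$a_index)] <- cat
  }
  for (cat in coding_cats) {
    fs <- feats[[cat]]
    if (nrow(fs) == 0) next
    hits <- overlap_pairs(elements, fs)
    for (k in seq_len(nrow(hits))) {
      i <- hits$a_index[k]
      hit_genes[[i]] <- union(hit_genes[[i]], fs$name[hits$b_index[k]])
    }
  }
  elements$category <- category
  elements$coding <- category %in% coding_cats
  elements$gene_ids <- hit_genes
  elements
}

# Flatten a per-gene feature extractor into one interval tibble
# (name = gene_id).
gene_feature_intervals <- function(genes, fn) {
  pieces <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    iv <- fn(g)
    if (nrow(iv) == 0) return(NULL)
    tibble::tibble(chrom = g$chrom, start = iv$start, end = iv$end,
                   name = g$gene_id)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0) {
    return(tibble::tibble(chrom = character(0), start = numeric(0),
                          end = numeric(0), name = character(0)))
  }
  as_intervals(dplyr::bind_rows(pieces))
}

# Complement of sorted disjoint intervals within [lo, hi).
gaps_within <- function(iv, lo, hi) {
  if (nrow(iv) == 0) return(tibble::tibble(start = lo, end = hi))
  iv <- collapse_intervals(iv)
  starts <- c(lo, iv$end)
  ends <- c(iv$start, hi)
  keep <- starts < ends
  tibble::tibble(start = starts[keep], end = ends[keep])
}
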