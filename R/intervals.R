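#' Validate and sort a tibble of genomic intervals
#'
#' Intervals use the BED convention throughout: 0-based starts, half-open
#' `[start, end)`. The returned tibble is sorted by `(chrom, start, end)`.
#'
#' @param x A data frame with columns `chrom`, `start`, `end` and optionally
#'   `name`. Extra columns are preserved.
#' @param chrom_sizes Optional named vector (or two-column data frame of
#'   `chrom`, `size`) of chromosome lengths; when given, intervals must lie
#'   within `[0, size)`.
#' @return A tibble of validated, sorted intervals.
#' @export
as_intervals <- function(x, chrom_sizes = NULL) {
  stopifnot(is.data.frame(x))
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss) > 0) {
    stop("interval table lacks column(s): ", paste(miss, collapse = ", "))
  }
  x <- tibble::as_tibble(x)
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  bad <- which(!is.finite(x$start) | !is.finite(x$end) |
                 x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  }
  if (!is.null(chrom_sizes)) {
    sizes <- as_chrom_sizes(chrom_sizes)
    sz <- sizes[x$chrom]
    if (anyNA(sz)) {
      stop("interval on unknown chromosome: ",
           paste(unique(x$chrom[is.na(sz)]), collapse = ", "))
    }
    over <- which(x$end > sz)
    if (length(over) > 0) {
      stop("interval(s) beyond chromosome end at row(s) ",
           paste(utils::head(over, 5), collapse = ", "))
    }
  }
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

as_chrom_sizes <- function(chrom_sizes) {
  if (is.data.frame(chrom_sizes)) {
    stats::setNames(as.numeric(chrom_sizes[[2]]), as.character(chrom_sizes[[1]]))
  } else {
    stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
}

#' Read intervals from a BED3/BED4 file
#'
#' @param path Path to a tab-separated BED file (no header). Columns beyond
#'   the fourth are ignored.
#' @param chrom_sizes Optional chromosome sizes for bounds validation.
#' @return A tibble with `chrom`, `start`, `end` and (when present) `name`,
#'   sorted by position.
#' @export
read_bed <- function(path, chrom_sizes = NULL) {
  stopifnot(file.exists(path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinate")
  }
  out <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = start,
    end = end
  )
  if (all(nf >= 4)) {
    out$name <- vapply(fields, `[[`, "", 4L)
  }
  as_intervals(out, chrom_sizes)
}

#' Write intervals to a BED file
#'
#' @param intervals Interval tibble (see [as_intervals()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- as_intervals(intervals)
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(intervals)) cols <- c(cols, "name")
  df <- intervals[cols]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  readr::write_tsv(df, path, col_names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path Path to tab-separated `chrom<TAB>length` text.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "size"),
                        col_types = "cd", progress = FALSE)
  stats::setNames(df$size, df$chrom)
}

# Convert an interval tibble to GRanges (1-based closed, as GRanges expects).
intervals_to_granges <- function(intervals) {
  GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start + 1, end = intervals$end)
  )
}

#' All overlapping pairs between two interval sets
#'
#' Reports every pair of intervals sharing at least one base, with the
#' overlap width. Half-open adjacency (`end == start`) does not overlap.
#'
#' @param a,b Interval tibbles.
#' @return Tibble with `a_index`, `b_index` (row indices into the sorted
#'   inputs) and `overlap_bp`.
#' @export
overlap_pairs <- function(a, b) {
  a <- as_intervals(a)
  b <- as_intervals(b)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(intervals_to_granges(a),
                                intervals_to_granges(b)))
  ai <- S4Vectors::queryHits(hits)
  bi <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  tibble::tibble(a_index = ai, b_index = bi, overlap_bp = ov)
}

# Logical: does each interval in `a` overlap anything in `b`?
overlaps_any <- function(a, b) {
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  gr_a <- intervals_to_granges(a)
  gr_b <- intervals_to_granges(b)
  suppressWarnings(IRanges::overlapsAny(gr_a, gr_b))
}

# Merge overlapping/adjacent intervals; returns total covered bp per set.
merged_span <- function(intervals) {
  if (nrow(intervals) == 0) return(0)
  gr <- GenomicRanges::reduce(intervals_to_granges(intervals))
  sum(as.numeric(GenomicRanges::width(gr)))
}
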