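# Small fixtures built in code, shared across test files.

# A 4-gene model on two chromosomes exercising both strands, UTRs and CDS.
tiny_genes <- function() {
  gene_models(
    gene_id = c("gA", "gB", "gC", "gD"),
    chrom = c("chr1", "chr1", "chr2", "chr2"),
    strand = c("+", "-", "+", "-"),
    start = c(10000, 40000, 5000, 30000),
    end = c(20000, 50000, 15000, 40000),
    exons = list(
      data.frame(start = c(10000, 15000), end = c(12000, 20000)),
      data.frame(start = c(40000, 47000), end = c(43000, 50000)),
      data.frame(start = 5000, end = 15000),
      data.frame(start = c(30000, 36000), end = c(33000, 40000))
    ),
    cds = list(
      data.frame(start = c(10500, 15000), end = c(12000, 19000)),
      data.frame(start = c(41000, 47000), end = c(43000, 49000)),
      data.frame(start = 6000, end = 14000),
      data.frame(start = c(31000, 36000), end = c(33000, 39000))
    ),
    utr5 = list(
      data.frame(start = 10000, end = 10500),
      data.frame(start = 49000, end = 50000),
      data.frame(start = 5000, end = 6000),
      data.frame(start = 39000, end = 40000)
    ),
    utr3 = list(
      data.frame(start = 19000, end = 20000),
      data.frame(start = 40000, end = 41000),
      data.frame(start = 14000, end = 15000),
      data.frame(start = 30000, end = 31000)
    )
  )
}

tiny_sizes <- function() c(chr1 = 100000, chr2 = 100000)

# Deterministic random interval set.
random_intervals <- function(n, seed, chroms = c("chr1", "chr2"),
                             max_pos = 9000, max_len = 120) {
  set.seed(seed)
  start <- sample.int(max_pos, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = start, end = start + len)
}

# Quadratic brute-force overlap oracle (half-open convention).
brute_overlaps <- function(a, b) {
  a <- as_intervals(a); b <- as_intervals(b)
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j]) {
        ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
        if (ov > 0) out[[length(out) + 1]] <- c(i, j, ov)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(a_index = integer(0), b_index = integer(0),
                          overlap_bp = numeric(0)))
  }
  m <- do.call(rbind, out)
  tibble::tibble(a_index = m[, 1], b_index = m[, 2], overlap_bp = m[, 3])
}

# A small genome with a strong GC gradient for matching tests.
tiny_genome <- function(seed = 1, len = 200000) {
  set.seed(seed)
  mk <- function() {
    blocks <- lapply(seq(0, len - 1, by = 5000), function(s) {
      gc <- 0.25 + 0.5 * (s / len)
      paste(c("A", "C", "G", "T")[sample.int(4, 5000, replace = TRUE,
              prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))],
            collapse = "")
    })
    Biostrings::DNAString(paste(unlist(blocks), collapse = ""))
  }
  g <- Biostrings::DNAStringSet(list(chr1 = mk(), chr2 = mk()))
  g
}

# Shared full-scale caller fixture: simulated once per test run and reused
# by the calibration, recovery and acceptance tests.
caller_fixture <- local({
  cache <- NULL
  function(seed = 11) {
    if (!is.null(cache) && cache$seed == seed) return(cache)
    cfg <- synth_config(seed = seed)
    sim <- simulate_genome(cfg)
    cmap <- simulate_contacts(cfg, sim)
    controls <- sample_gc_length_matched(sim$elements, sim$genome,
                                         reps = 40, seed = cfg$seed)
    ctrl_anchors <- bin_anchors(
      dplyr::rename(controls[c("chrom", "start", "end", "source")],
                    name = "source"), cfg$bin_size)
    bg <- locus_profiles(cmap$contacts, ctrl_anchors,
                         cfg$window)[c("chrom", "distance", "contact")]
    null <- fit_contact_null(bg)
    prof <- locus_profiles(cmap$contacts, bin_anchors(sim$elements),
                           cfg$window)
    calls <- correct_and_call(interaction_pvalues(prof, null), fdr = 0.01)
    cache <<- list(seed = seed, cfg = cfg, sim = sim, cmap = cmap,
                   controls = controls, null = null, prof = prof,
                   calls = calls)
    cache
  }
})

unordered_pair_key <- function(chrom, a, b) {
  paste(chrom, pmin(a, b), pmax(a, b))
}
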