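test_that("gc_content counts G+C over unambiguous bases", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AATTGCGCACGTACGTNNNN"))
  iv <- tibble::tibble(chrom = "chr1",
                       start = c(0, 4, 8, 14),
                       end = c(4, 8, 16, 20))
  expect_equal(gc_content(iv[1, ], g), 0)     # AATT
  expect_equal(gc_content(iv[2, ], g), 1)     # GCGC
  expect_equal(gc_content(iv[3, ], g), 0.5)   # ACGTACGT
  expect_equal(gc_content(iv[4, ], g), 0.5)   # GT + NNNN: Ns excluded
  expect_error(gc_content(tibble::tibble(chrom = "chr1", start = 16, end = 20), g),
               "no unambiguous bases")
})

test_that("GC/length-matched controls honour every matching invariant", {
  genome <- tiny_genome(2)
  set.seed(42)
  els <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = 15),
                        start = round(runif(30, 0, 190000)))
  els$end <- els$start + sample(100:400, 30, replace = TRUE)
  els$name <- paste0("E", 1:30)
  src_gc <- gc_content(els, genome)

  ctr <- sample_gc_length_matched(els, genome, reps = 12, gc_tol = 0.05,
                                  seed = 9)
  expect_equal(attr(ctr, "total_drawn"), 30 * 12)
  by_src <- split(ctr, ctr$source)
  for (nm in names(by_src)) {
    i <- match(nm, els$name)
    expect_true(all(by_src[[nm]]$chrom == els$chrom[i]))
    expect_true(all(by_src[[nm]]$end - by_src[[nm]]$start ==
                      els$end[i] - els$start[i]))
    expect_true(all(abs(by_src[[nm]]$gc - src_gc[i]) < 0.05 |
                      by_src[[nm]]$relaxed))
  }
  # no two identical (chrom, start, end) triples after dedup
  expect_false(any(duplicated(ctr[c("chrom", "start", "end")])))
  # deterministic under the seed, different under another
  ctr2 <- sample_gc_length_matched(els, genome, reps = 12, seed = 9)
  expect_identical(ctr, ctr2)
  ctr3 <- sample_gc_length_matched(els, genome, reps = 12, seed = 10)
  expect_false(identical(ctr$start, ctr3$start))
  # per-element substreams: adding an element leaves earlier draws intact
  ctr4 <- sample_gc_length_matched(els[1:10, ], genome, reps = 12, seed = 9)
  expect_equal(ctr4$start[ctr4$source == "E3"], ctr$start[ctr$source == "E3"])
  # control GC distribution tracks the source distribution
  ks <- suppressWarnings(stats::ks.test(ctr$gc, rep(src_gc, each = 12)))
  expect_lt(unname(ks$statistic), 0.1)
})

test_that("conserved-region calling matches a per-base oracle", {
  # constant high track -> one region spanning the chromosome
  t1 <- tibble::tibble(chrom = "c", start = 0, end = 100, score = 0.5)
  r1 <- call_conserved_regions(t1)
  expect_equal(nrow(r1), 1)
  expect_equal(c(r1$start, r1$end), c(0, 100))
  # runs must be strictly longer than min_len
  t2 <- tibble::tibble(chrom = "c", start = c(0, 50), end = c(15, 71),
                       score = c(0.9, 0.9))
  r2 <- call_conserved_regions(t2)
  expect_equal(nrow(r2), 1)
  expect_equal(r2$start, 50)
  expect_equal(nrow(call_conserved_regions(
    tibble::tibble(chrom = "c", start = 0, end = 20, score = 0.9))), 0)

  # random step track vs per-base scan
  set.seed(8)
  bounds <- sort(sample(1:499, 60))
  starts <- c(0, bounds)
  ends <- c(bounds, 500)
  tr <- tibble::tibble(chrom = "c", start = starts, end = ends,
                       score = round(runif(length(starts)), 2))
  got <- call_conserved_regions(tr, min_len = 10, threshold = 0.4)
  base_scores <- numeric(500)
  for (i in seq_len(nrow(tr))) {
    base_scores[(tr$start[i] + 1):tr$end[i]] <- tr$score[i]
  }
  rl <- rle(base_scores > 0.4)
  ends_rl <- cumsum(rl$lengths)
  starts_rl <- ends_rl - rl$lengths
  keep <- rl$values & rl$lengths > 10
  expect_equal(got$start, starts_rl[keep])
  expect_equal(got$end, ends_rl[keep])
})

test_that("mean_conservation integrates runs with zero-filled gaps", {
  tr <- tibble::tibble(chrom = "c", start = c(10, 30), end = c(20, 40),
                       score = c(0.8, 0.4))
  iv <- tibble::tibble(chrom = "c", start = c(0, 10, 15, 0),
                       end = c(50, 20, 35, 10))
  expect_equal(mean_conservation(iv, tr),
               c((0.8 * 10 + 0.4 * 10) / 50, 0.8, (0.8 * 5 + 0.4 * 5) / 20, 0))
})

test_that("conservation-matched sets land on matched-score territory", {
  sizes <- c(chr1 = 1e6, chr2 = 1e6)
  set.seed(3)
  isl_start <- sort(sample(seq(0, 990000, by = 2000), 150))
  track <- tibble::tibble(chrom = rep(c("chr1", "chr2"), each = 150),
                          start = rep(isl_start, 2),
                          end = rep(isl_start + 800, 2), score = 0.8)
  els <- tibble::tibble(chrom = "chr1", start = isl_start[1:40] + 100,
                        end = isl_start[1:40] + 300,
                        name = paste0("E", 1:40))
  ms <- sample_conservation_matched(els, track, sizes, n_sets = 25, seed = 4)
  expect_equal(length(unique(ms$set)), 25)
  expect_equal(nrow(ms), 25 * 40)
  expect_true(all(ms$end - ms$start == 200))
  # planted two-level track: controls must sit on islands to match score
  on_island <- overlaps_any(ms[c("chrom", "start", "end")],
                            track[c("chrom", "start", "end")])
  expect_gt(mean(on_island), 0.95)
  # constant track degenerates to pure length matching
  flat <- tibble::tibble(chrom = c("chr1", "chr2"), start = 0, end = 1e6,
                         score = 0.5)
  ms2 <- sample_conservation_matched(els, flat, sizes, n_sets = 3, seed = 4)
  expect_equal(nrow(ms2), 3 * 40)
  expect_false(any(ms2$relaxed))
})
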