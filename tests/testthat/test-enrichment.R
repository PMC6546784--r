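# independent two-sided Fisher oracle: enumerate the hypergeometric
# distribution over all tables with the observed margins
fisher_oracle_p <- function(A, B, C, D) {
  m <- A + B; n <- C + D; k <- A + C
  x <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(x, m, n, k)
  p_obs <- stats::dhyper(A, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

make_region_row <- function(n, chrom = "c", width = 10, gap = 100) {
  start <- seq(0, by = gap, length.out = n)
  tibble::tibble(chrom = chrom, start = start, end = start + width)
}

test_that("binomial enrichment matches direct tail summation", {
  # annotation covering the whole genome: certain overlap
  els <- make_region_row(10)
  ann_full <- tibble::tibble(chrom = "c", start = 0, end = 2000)
  r <- binomial_enrichment(els, ann_full, 2000)
  expect_equal(r$s, 10)
  expect_equal(r$p_genome, 1)
  expect_equal(r$p.value, 1)
  expect_equal(r$fold, 1)

  # n = 10, s = 5, p = 0.2 against term-by-term summation
  ann <- make_region_row(5, gap = 100)           # overlaps elements 1..5
  genome_length <- sum(ann$end - ann$start) / 0.2
  r2 <- binomial_enrichment(els, ann, genome_length)
  expect_equal(r2$s, 5)
  expect_equal(r2$p_genome, 0.2)
  direct <- sum(vapply(5:10, function(k) choose(10, k) * 0.2^k * 0.8^(10 - k),
                       numeric(1)))
  expect_equal(r2$p.value, direct, tolerance = 1e-12)
  expect_equal(r2$fold, (5 / 10) / 0.2)

  # no overlap: Pr(k >= 0) = 1
  far <- tibble::tibble(chrom = "c", start = 5e5, end = 5e5 + 10)
  expect_equal(binomial_enrichment(els, far, 1e6)$p.value, 1)
  expect_error(binomial_enrichment(els[0, ], ann, 1e6), "empty")

  # p-value is monotone decreasing in s at fixed (n, p)
  ps <- vapply(1:9, function(s) {
    binomial_enrichment(els, make_region_row(s), 5000)$p.value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("fisher_conserved reproduces known tables and flags degeneracy", {
  els <- make_region_row(15)
  ann <- make_region_row(10)                     # elements 1..10 overlap
  bg <- make_region_row(25, gap = 100)
  bg$start <- bg$start + 5; bg$end <- bg$end + 5 # background 1..10 overlap too
  r <- fisher_conserved(els, ann, bg)
  expect_equal(c(r$A, r$B, r$C, r$D), c(10, 10, 5, 15))
  expect_equal(r$odds_ratio, (10 * 15) / (10 * 5))
  expect_equal(r$p.value, fisher_oracle_p(10, 10, 5, 15), tolerance = 1e-12)

  # A = C and B = D: no association
  els2 <- make_region_row(10)
  ann2 <- make_region_row(5)
  bg2 <- make_region_row(10)
  bg2$start <- bg2$start + 2; bg2$end <- bg2$end + 2  # 5 of 10 overlap
  r2 <- fisher_conserved(els2, ann2, bg2)
  expect_equal(r2$odds_ratio, 1)

  # B = 0 with A > 0: infinite OR, Haldane CI, flagged
  bg3 <- make_region_row(10)
  bg3$start <- bg3$start + 5e5; bg3$end <- bg3$end + 5e5
  r3 <- fisher_conserved(els2, ann2, bg3)
  expect_equal(r3$odds_ratio, Inf)
  expect_true(r3$haldane)
  expect_true(is.finite(r3$conf.low))

  # zero margin errors name the margin
  expect_error(fisher_conserved(els2, make_region_row(1, chrom = "nowhere"),
                                bg2), "zero margin")
})

test_that("fisher p agrees with hypergeometric enumeration on small grids", {
  for (n1 in c(1, 3, 7, 12)) {
    for (n2 in c(1, 4, 9, 12)) {
      for (A in 0:n1) {
        for (B in 0:n2) {
          C <- n1 - A; D <- n2 - B
          if (A + B == 0 || C + D == 0) next
          p_pkg <- stats::fisher.test(matrix(c(A, B, C, D), 2,
                                             byrow = TRUE))$p.value
          expect_equal(p_pkg, fisher_oracle_p(A, B, C, D), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("permutation OR distribution behaves at identity and planted truth", {
  set.seed(14)
  els <- make_region_row(60, gap = 500)
  ann <- els[1:30, ]                              # half the elements overlap
  bg <- make_region_row(200, gap = 500)
  bg$start <- bg$start + 120; bg$end <- bg$end + 120
  # matched sets: replicate 1 is the element set itself -> its OR equals
  # the observed OR
  neutral <- lapply(2:60, function(s) {
    d <- els
    d$start <- d$start + 7 + 13 * s; d$end <- d$end + 7 + 13 * s
    d
  })
  sets <- c(list(els), neutral)
  dist <- permutation_or(els, ann, sets, bg)
  expect_equal(dist$null_or[1], dist$observed$odds_ratio)
  expect_equal(length(dist$null_or) + dist$n_degenerate, 60)
  expect_gte(dist$p_empirical, 1 / 61)
  td <- tidy(dist)
  expect_equal(nrow(td), length(dist$null_or))
  gl <- glance(dist)
  expect_equal(gl$observed_or, dist$observed$odds_ratio)

  # planted enrichment: observed OR should beat >=99% of neutral sets
  sizes <- c(chr1 = 1e6)
  set.seed(15)
  peak_start <- seq(0, 990000, by = 5000)
  ann2 <- tibble::tibble(chrom = "chr1", start = peak_start,
                         end = peak_start + 500)   # 10% genome coverage
  in_peak <- runif(120) < 0.4
  el_start <- ifelse(in_peak,
                     sample(peak_start, 120, replace = TRUE) + 100,
                     sample(peak_start, 120, replace = TRUE) + 1000)
  els2 <- tibble::tibble(chrom = "chr1", start = el_start,
                         end = el_start + 200)
  bg2_start <- sample(seq(0, 995000, by = 7), 800)
  bg2 <- tibble::tibble(chrom = "chr1", start = bg2_start,
                        end = bg2_start + 200)
  null_sets <- lapply(1:300, function(s) {
    st <- sample(seq(0, 995000), 120)
    tibble::tibble(chrom = "chr1", start = st, end = st + 200)
  })
  dist2 <- permutation_or(els2, ann2, null_sets, bg2)
  expect_gte(mean(dist2$observed$odds_ratio > dist2$null_or), 0.99)
  expect_lt(dist2$p_empirical, 0.02)
})

test_that("empirical permutation p is uniform under a neutral annotation", {
  set.seed(77)
  mk_set <- function(n = 300) {
    st <- sample(seq(0, 995000), n)
    tibble::tibble(chrom = "chr1", start = st, end = st + 200)
  }
  bg <- mk_set(800)
  p_emp <- vapply(1:120, function(r) {
    els <- mk_set()                       # elements exchangeable with nulls
    null_sets <- lapply(1:99, function(s) mk_set())
    st <- sample(seq(0, 999000, by = 3), 150)
    ann <- tibble::tibble(chrom = "chr1", start = st, end = st + 800)
    permutation_or(els, ann, null_sets, bg)$p_empirical
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p_emp, "punif"))
  expect_gt(ks$p.value, 0.01)
})
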