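test_that("window background equals a quadratic all-pairs oracle", {
  set.seed(12)
  genes <- gene_models(gene_id = paste0("g", 1:80),
                       chrom = sample(c("chr1", "chr2"), 80, replace = TRUE),
                       strand = sample(c("+", "-"), 80, replace = TRUE),
                       start = st <- sample.int(8e6, 80),
                       end = st + sample(2e4:8e4, 80, replace = TRUE))
  els <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 25, replace = TRUE),
                        start = es <- sample.int(8e6, 25), end = es + 300)
  got <- build_window_background(els, genes, window = 1e6)
  want <- character(0)
  for (i in seq_len(nrow(els))) {
    for (j in seq_len(nrow(genes))) {
      if (els$chrom[i] == genes$chrom[j] &&
          genes$start[j] < els$end[i] + 1e6 &&
          genes$end[j] > els$start[i] - 1e6) {
        want <- c(want, genes$gene_id[j])
      }
    }
  }
  expect_setequal(got, unique(want))
  # a gene overlapping an element is always included
  on_el <- gene_models("hit", els$chrom[1], "+", els$start[1] - 50,
                       els$end[1] + 50)
  expect_true("hit" %in% build_window_background(els, on_el))
})

test_that("covariate-free logistic OR equals the sample odds ratio", {
  # A=20, B=80, C=30, D=870 -> OR = 7.25
  ann <- tibble::tibble(
    gene_id = paste0("g", 1:1000),
    target = c(rep(1, 20), rep(0, 80), rep(1, 30), rep(0, 870)),
    in_set = c(rep(1, 100), rep(0, 900)),
    cds_length = 1500)
  r <- logistic_enrichment(ann, use_covariate = FALSE)
  expect_equal(r$odds_ratio, (20 * 870) / (80 * 30), tolerance = 1e-6)
  expect_equal(c(r$A, r$B, r$C, r$D), c(20, 80, 30, 870))
  # constant covariate degrades to the covariate-free fit
  r2 <- logistic_enrichment(ann, use_covariate = TRUE)
  expect_equal(r2$odds_ratio, r$odds_ratio, tolerance = 1e-6)
  expect_equal(r2$p.value, r$p.value, tolerance = 1e-6)

  # equality holds across random non-degenerate 2x2 configurations
  set.seed(20)
  for (i in 1:30) {
    cells <- rmultinom(1, 400, c(0.1, 0.2, 0.25, 0.45))[, 1] + 1
    ann_i <- tibble::tibble(
      gene_id = seq_len(sum(cells)),
      target = rep(c(1, 0, 1, 0), cells),
      in_set = rep(c(1, 1, 0, 0), cells))
    ri <- logistic_enrichment(ann_i, use_covariate = FALSE)
    expect_equal(ri$odds_ratio,
                 (cells[1] * cells[4]) / (cells[2] * cells[3]),
                 tolerance = 1e-6)
  }
  expect_error(logistic_enrichment(dplyr::mutate(ann, in_set = 0)),
               "does not vary")
  expect_error(logistic_enrichment(ann[1:20, ]), "at least 50")
})

test_that("separation is flagged rather than silently reported", {
  ann <- tibble::tibble(gene_id = 1:200,
                        target = c(rep(1, 50), rep(0, 150)),
                        in_set = c(rep(1, 50), rep(0, 150)))
  expect_warning(r <- logistic_enrichment(ann), "separation")
  expect_true(r$separated)
  expect_equal(r$odds_ratio, Inf)
})

test_that("logistic and Fisher agree on direction and significance", {
  set.seed(30)
  agree_dir <- agree_sig <- logical(0)
  for (i in 1:150) {
    or_true <- exp(runif(1, -1.5, 1.5))
    n <- 600
    target <- rbinom(n, 1, 0.2)
    p0 <- 0.1
    p1 <- or_true * p0 / (1 - p0) / (1 + or_true * p0 / (1 - p0))
    in_set <- rbinom(n, 1, ifelse(target == 1, p1, p0))
    if (length(unique(in_set)) < 2) next
    ann <- tibble::tibble(gene_id = 1:n, target = target, in_set = in_set)
    A <- sum(target & in_set); B <- sum(!target & in_set)
    C <- sum(target & !in_set); D <- sum(!target & !in_set)
    if (A == 0 || B == 0 || C == 0 || D == 0) next
    lg <- logistic_enrichment(ann)
    fp <- stats::fisher.test(matrix(c(A, B, C, D), 2, byrow = TRUE))$p.value
    agree_dir <- c(agree_dir, (lg$odds_ratio > 1) == ((A * D) / (B * C) > 1))
    agree_sig <- c(agree_sig, (lg$p.value < 0.05) == (fp < 0.05))
  }
  expect_true(all(agree_dir))
  expect_gt(mean(agree_sig), 0.95)
})

test_that("the coding-length covariate absorbs a planted length confound", {
  set.seed(40)
  shrunk <- replicate(50, {
    n <- 2000
    cds <- rlnorm(n, log(1500), 0.8)
    # membership driven purely by coding length; targets random
    in_set <- rbinom(n, 1, plogis(-3 + 1.2 * scale(log(cds))))
    target <- rbinom(n, 1, plogis(-2 + 0.8 * scale(log(cds))))
    if (length(unique(in_set)) < 2 || length(unique(target)) < 2) {
      return(NA_real_)
    }
    ann <- tibble::tibble(gene_id = 1:n, target = target,
                          in_set = in_set, cds_length = cds)
    raw <- suppressWarnings(logistic_enrichment(ann, use_covariate = FALSE))
    adj <- suppressWarnings(logistic_enrichment(ann, use_covariate = TRUE))
    abs(log(adj$odds_ratio)) - abs(log(raw$odds_ratio))
  })
  expect_lt(mean(shrunk, na.rm = TRUE), 0)
})

test_that("grid correction adjusts one BH family over tested cells", {
  grid <- tibble::tibble(class = rep(c("HAR", "HGE"), each = 2),
                         set = rep(c("ASD", "DD"), 2),
                         p.value = c(0.001, 0.01, 0.02, 0.9))
  out <- correct_grid(grid)
  expect_equal(out$q, c(0.004, 0.02, 4 * 0.02 / 3, 0.9))
  expect_equal(attr(out, "family_size"), 4)
  # equal p-values get equal q
  eq <- correct_grid(tibble::tibble(class = "a", set = letters[1:5],
                                    p.value = rep(0.03, 5)))
  expect_true(all(eq$q == 0.03))
  # untested cells stay NA and are outside the family
  grid$p.value[2] <- NA
  out2 <- correct_grid(grid)
  expect_true(is.na(out2$q[2]))
  expect_equal(attr(out2, "family_size"), 3)
  # 4 classes x 10 sets -> family of 40
  big <- tidyr::expand_grid(class = paste0("c", 1:4), set = paste0("s", 1:10))
  big$p.value <- runif(40)
  expect_equal(attr(correct_grid(big), "family_size"), 40)
})
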