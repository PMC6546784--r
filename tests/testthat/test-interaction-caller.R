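toy_contacts <- function() {
  # 300-bin chromosome with decaying band contacts
  trip <- list()
  set.seed(31)
  for (k in 1:99) {
    i <- 0:(300 - 1 - k)
    trip[[k]] <- tibble::tibble(chrom = "chrT", bin1 = i, bin2 = i + k,
                                count = rweibull(length(i), 3, 50 / k))
  }
  contact_matrix(dplyr::bind_rows(trip), bin_size = 10000,
                 chrom_sizes = c(chrT = 3e6))
}

test_that("bin_anchors maps elements to every touched bin", {
  a <- bin_anchors(tibble::tibble(chrom = "c", start = 25000, end = 26000))
  expect_equal(a$anchor, 2)
  b <- bin_anchors(tibble::tibble(chrom = "c", start = 9500, end = 10500))
  expect_equal(b$anchor, c(0, 1))
  s16 <- bin_anchors(tibble::tibble(chrom = "c", start = 41200, end = 41216))
  expect_equal(nrow(s16), 1)   # a 16 bp element occupies exactly one bin
})

test_that("locus profiles have the printed candidate geometry", {
  cm <- toy_contacts()
  interior <- locus_profile(cm, "chrT", 150)
  expect_equal(nrow(interior), 198)
  expect_equal(sort(unique(abs(interior$offset))), 1:99)
  expect_false(any(interior$offset == 0))
  edge <- locus_profile(cm, "chrT", 3)
  expect_equal(nrow(edge), 102)  # 3 upstream + 99 downstream
  expect_equal(interior$distance[interior$offset == 7], 70000)
  expect_true(all(interior$contact >= 0))
})

test_that("Weibull MLE recovers truth and agrees with fitdistrplus", {
  set.seed(5)
  x <- rweibull(5000, shape = 2, scale = 5)
  fit <- weibull_mle(x)
  expect_lt(abs(fit[["shape"]] - 2) / 2, 0.05)
  expect_lt(abs(fit[["scale"]] - 5) / 5, 0.05)
  ref <- suppressMessages(fitdistrplus::fitdist(x, "weibull"))$estimate
  expect_equal(unname(fit[["shape"]]), unname(ref[["shape"]]), tolerance = 1e-3)
  expect_equal(unname(fit[["scale"]]), unname(ref[["scale"]]), tolerance = 1e-3)
  expect_error(weibull_mle(rep(2, 100)), "identical")
  expect_error(weibull_mle(c(0, 1, 2)), "positive")
})

test_that("the null fit ignores zeros and pools sparse cells", {
  set.seed(6)
  x <- rweibull(400, 2.5, 10)
  prof <- tibble::tibble(chrom = "c", distance = 10000, contact = x)
  prof0 <- tibble::tibble(chrom = "c", distance = 10000,
                          contact = c(x, rep(0, 400)))
  f1 <- fit_contact_null(prof, min_obs = 30)
  f2 <- fit_contact_null(prof0, min_obs = 30)
  expect_equal(f1$shape, f2$shape)
  expect_equal(f1$scale, f2$scale)
  expect_equal(f2$zero_frac, 0.5)

  # sparse cell pooled with neighbours
  sparse <- dplyr::bind_rows(
    tibble::tibble(chrom = "c", distance = 10000, contact = rweibull(100, 2, 5)),
    tibble::tibble(chrom = "c", distance = 20000, contact = rweibull(5, 2, 5)),
    tibble::tibble(chrom = "c", distance = 30000, contact = rweibull(100, 2, 5)))
  f3 <- fit_contact_null(sparse, min_obs = 30)
  expect_true(f3$pooled[f3$distance == 20000])
  expect_false(f3$pooled[f3$distance == 10000])
  expect_error(fit_contact_null(
    tibble::tibble(chrom = "c", distance = 10000, contact = rep(0, 50))),
    "no positive contacts")
})

test_that("survival p-values follow the closed form and are monotone", {
  null <- fit_contact_null(tibble::tibble(
    chrom = "c", distance = 10000,
    contact = rweibull(2000, 2, 3)))
  grid <- tibble::tibble(element = "e", chrom = "c", anchor = 5,
                         candidate = 6, offset = 1, distance = 10000,
                         contact = c(0, 0.5, 1, 2, 4, 8))
  p <- interaction_pvalues(grid, null)$p
  expect_equal(p[1], 1)
  expect_equal(p[-1], exp(-(grid$contact[-1] / null$scale)^null$shape))
  expect_true(all(diff(p) < 0))
  # median of the fitted null maps to p = 0.5
  med <- null$scale * log(2)^(1 / null$shape)
  grid2 <- grid[1, ]; grid2$contact <- med
  expect_equal(interaction_pvalues(grid2, null)$p, 0.5)
  # unresolved (chromosome, distance) is an error
  bad <- grid; bad$distance <- 50000
  expect_error(interaction_pvalues(bad, null), "does not cover")
})

test_that("BH correction matches hand-computed step-up values", {
  calls <- tibble::tibble(p = c(0.001, 0.01, 0.02, 0.9))
  got <- correct_and_call(calls, fdr = 0.01)
  expect_equal(got$q, c(0.004, 0.02, 4 * 0.02 / 3, 0.9))
  expect_equal(got$significant, c(TRUE, FALSE, FALSE, FALSE))
  all_one <- correct_and_call(tibble::tibble(p = rep(1, 20)), fdr = 0.01)
  expect_false(any(all_one$significant))
})

test_that("target assignment honours mode semantics and call order", {
  genes <- gene_models(gene_id = c("G1", "G2"), chrom = "chrT",
                       strand = c("+", "+"),
                       start = c(500000, 800000), end = c(520000, 820000))
  # G1 promoter [498000, 500000) -> bin 49; G2 promoter -> bin 79
  els <- tibble::tibble(chrom = "chrT",
                        start = c(100000, 501000, 900000),
                        end = c(100300, 501200, 900200),
                        name = c("distal", "inside_G1", "lonely"))
  calls <- tibble::tibble(
    element = c("distal", "distal", "inside_G1", "lonely"),
    chrom = "chrT", anchor = c(10, 10, 50, 90),
    candidate = c(49, 79, 79, 60),
    contact = 5, p = 1e-6,
    q = c(1e-4, 2e-4, 3e-4, 0.5),
    significant = c(TRUE, TRUE, TRUE, FALSE))
  tg <- assign_targets(calls, els, genes, mode = "promoter_split",
                       chrom_sizes = c(chrT = 3e6))
  # distal element: interaction targets via both promoters
  expect_setequal(tg$gene_id[tg$element == "distal"], c("G1", "G2"))
  expect_true(all(tg$evidence[tg$element == "distal"] == "interaction"))
  # element inside G1 body (not promoter) keeps its interaction target
  expect_equal(tg$gene_id[tg$element == "inside_G1"], "G2")
  # element with no significant call is absent
  expect_false("lonely" %in% tg$element)

  # promoter-overlapping element is assigned directly under promoter_split
  els2 <- els
  els2$start[2] <- 499000; els2$end[2] <- 499200
  tg2 <- assign_targets(calls, els2, genes, mode = "promoter_split",
                        chrom_sizes = c(chrT = 3e6))
  row <- tg2[tg2$element == "inside_G1" & tg2$gene_id == "G1", ]
  expect_equal(row$evidence, "coding_direct")

  # adult mode: interaction only, even for promoter-overlapping elements
  tg3 <- assign_targets(calls, els2, genes, mode = "adult_promoter_only",
                        chrom_sizes = c(chrT = 3e6))
  expect_true(all(tg3$evidence == "interaction"))

  # stable under permutation of call order
  perm <- calls[sample.int(nrow(calls)), ]
  tg4 <- assign_targets(perm, els, genes, mode = "promoter_split",
                        chrom_sizes = c(chrT = 3e6))
  expect_equal(tg4, tg)
})

test_that("fetal_full combines coding-direct and interaction evidence", {
  fx <- caller_fixture()
  tg <- assign_targets(fx$calls, fx$sim$elements, fx$sim$genes,
                       mode = "fetal_full", bin_size = fx$cfg$bin_size,
                       chrom_sizes = fx$sim$chrom_sizes)
  expect_true(all(c("coding_direct", "interaction") %in% tg$evidence))
  cls <- classify_elements(fx$sim$elements, fx$sim$genes, fx$sim$chrom_sizes)
  coding_els <- cls$name[cls$coding]
  # interaction evidence only for noncoding elements in this mode
  expect_false(any(tg$element[tg$evidence == "interaction"] %in% coding_els))
  # every interaction row traces to a significant call in a promoter bin
  prom <- promoter_regions(fx$sim$genes, 2000, fx$sim$chrom_sizes)
  inter <- tg[tg$evidence == "interaction", ]
  sig <- fx$calls[fx$calls$significant, ]
  for (i in seq_len(min(nrow(inter), 20))) {
    rows <- sig[sig$element == inter$element[i], ]
    bins <- tibble::tibble(chrom = rows$chrom, start = rows$candidate * 1e4,
                           end = (rows$candidate + 1) * 1e4)
    pg <- prom[prom$name == inter$gene_id[i], ]
    expect_true(any(overlaps_any(bins, pg)))
  }
})
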