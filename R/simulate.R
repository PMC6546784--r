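#' Configuration for the synthetic-data generator
#'
#' Bundles every parameter of the planted-truth simulators with defaults
#' matching the study conditions the pipeline is designed for: 10 kb
#' contact bins with 1 Mb windows, 40 GC-matched controls per element at
#' <5% GC difference, conserved regions called at score >0.40 over >20 bp,
#' a 3x contact fold on planted loops, a planted annotation odds ratio of
#' 3, a planted stage-matched expression shift of 0.128 Z-units on 500 of
#' 4125 orthologs, and a -0.05 event-score breakpoint shift on 200 genes.
#'
#' @param seed Integer master seed; every generator derives independent
#'   substreams from it.
#' @param chrom_lengths Named vector of chromosome lengths in bp.
#' @param ... Overrides for any default listed below.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1,
                         chrom_lengths = c(chrS1 = 20e6, chrS2 = 20e6),
                         ...) {
  cfg <- list(
    seed = seed,
    chrom_lengths = chrom_lengths,
    bin_size = 10000,
    window = 1e6,
    sequence = TRUE,
    # GC landscape: gc(pos) = gc_base + gc_amplitude * sin(2*pi*pos/gc_period)
    gc_base = 0.41, gc_amplitude = 0.10, gc_period = 2e6,
    # elements (named vector = one class per name)
    n_elements = c(HAR = 1000),
    element_meanlog = log(250), element_sdlog = 0.6, element_min_len = 16,
    # genes
    n_genes = 400, gene_min_len = 5000, gene_max_len = 50000,
    exons_per_gene = 2:6,
    # conservation islands
    island_frac = 0.05, island_len = 500,
    island_score_range = c(0.6, 0.95), decoy_score_range = c(0.05, 0.35),
    frac_on_islands = 0.9,
    # annotation peaks and planted enrichment
    n_peaks = 4000, peak_len = 1000, annotation_or = 3.0,
    # contact model
    decay_alpha = 1.0, dispersion_shape = 4, scale0 = 100,
    zero_prob_near = 0.05, zero_prob_far = 0.25,
    n_loops = 100, loop_fold = 3,
    # two-species expression atlases (event scores in (0,1))
    human_scores = c(0.12, 0.20, 0.30, 0.38, 0.46, 0.54, 0.63, 0.76, 0.85, 0.93),
    other_scores = c(0.10, 0.22, 0.32, 0.40, 0.48, 0.51, 0.60, 0.70, 0.77, 0.90),
    matched_pairs = data.frame(human_score = c(0.46, 0.54, 0.76),
                               other_score = c(0.48, 0.51, 0.77)),
    n_orthologs = 4125, deltaz_set_size = 500, deltaz_shift = 0.128,
    stage_noise_sd = 0.2,
    # breakpoint table
    breakpoint_set_size = 200, breakpoint_background_size = 3000,
    breakpoint_shift = -0.05, breakpoint_sd = 0.1,
    # dN/dS
    dnds_set_median = 0.2, dnds_background_median = 0.5, dnds_sdlog = 0.5,
    # bulk developmental atlas
    n_bulk_samples_per_period = 60, bulk_set_size = 150, bulk_shift_sd = 1,
    # single cells
    n_clusters = 6, cells_per_cluster = 40, n_cell_genes = 1000,
    marker_set_size = 100, marker_fold = 5, marker_cluster = "cluster3",
    # gene sets for logistic enrichment
    n_background_genes = 5000, n_target_genes = 800, geneset_or = 3.0,
    geneset_base_rate = 0.05,
    n_modules = 100, module_size = 30, module_or = 7
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown config field(s): ",
                                paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "synth_config")
}

# Random DNA with a sinusoidal GC landscape, one chromosome.
random_chromosome <- function(len, gc_base, gc_amplitude, gc_period,
                              block = 10000) {
  starts <- seq(0, len - 1, by = block)
  pieces <- vapply(starts, function(s) {
    n <- min(block, len - s)
    gc <- gc_base + gc_amplitude * sin(2 * pi * (s + n / 2) / gc_period)
    gc <- min(max(gc, 0.05), 0.95)
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(c("A", "C", "G", "T")[sample.int(4, n, replace = TRUE, prob = probs)],
          collapse = "")
  }, character(1))
  Biostrings::DNAString(paste(pieces, collapse = ""))
}

# Uniformly place n intervals of the given lengths on the genome
# (chromosomes weighted by length).
place_uniform <- function(n, lens, sizes) {
  chroms <- names(sizes)
  chr <- sample(chroms, n, replace = TRUE, prob = sizes / sum(sizes))
  max_start <- sizes[chr] - lens
  start <- floor(stats::runif(n, 0, pmax(max_start, 0) + 1))
  tibble::tibble(chrom = chr, start = start, end = start + lens)
}

#' Simulate a genome with genes, conservation and annotated elements
#'
#' Generates (deterministically given the config seed) a genome whose GC
#' content varies along each chromosome, gene models with exon/CDS
#' structure, a conservation track made of high-scoring islands plus
#' low-scoring decoy runs, regulatory annotation peaks, and element sets
#' placed so that the element-vs-conserved-background annotation overlap
#' attains a configured odds ratio. All planted facts are returned in
#' `$truth`.
#'
#' @param config A [synth_config()].
#' @return List with `genome` (NULL when `config$sequence` is FALSE),
#'   `chrom_sizes`, `genes`, `conservation`, `conserved_regions`,
#'   `annotation`, `elements` (tibble with `name`, `class`), `truth`.
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  sizes <- as_chrom_sizes(config$chrom_lengths)
  if (any(sizes <= config$gene_max_len)) stop("chromosomes too short for genes")
  set.seed(derive_seed(config$seed, 101))

  genome <- NULL
  if (isTRUE(config$sequence)) {
    genome <- Biostrings::DNAStringSet(lapply(sizes, function(L) {
      random_chromosome(L, config$gc_base, config$gc_amplitude, config$gc_period)
    }))
    names(genome) <- names(sizes)
  }

  # gene models: non-overlapping bodies on a jittered grid
  n_genes <- config$n_genes
  per_chr <- table(sample(names(sizes), n_genes, replace = TRUE,
                          prob = sizes / sum(sizes)))
  gene_rows <- list()
  gi <- 0
  for (chr in names(per_chr)) {
    k <- per_chr[[chr]]
    if (k == 0) next
    slots <- seq(0, sizes[[chr]] - config$gene_max_len - 1,
                 length.out = max(k, 2))[seq_len(k)]
    for (s in slots) {
      gi <- gi + 1
      len <- floor(stats::runif(1, config$gene_min_len, config$gene_max_len))
      start <- floor(s + stats::runif(1, 0, config$gene_max_len / 4))
      end <- min(start + len, sizes[[chr]] - 1)
      strand <- sample(c("+", "-"), 1)
      n_ex <- sample(config$exons_per_gene, 1)
      bounds <- floor(seq(start, end, length.out = 2 * n_ex))
      ex <- tibble::tibble(start = bounds[seq(1, 2 * n_ex, 2)],
                           end = bounds[seq(2, 2 * n_ex, 2)])
      ex <- ex[ex$end > ex$start, ]
      utr <- min(200, floor((ex$end[1] - ex$start[1]) / 2))
      cds <- clip_intervals(ex, ex$start[1] + utr,
                            ex$end[nrow(ex)] - utr)
      gene_rows[[gi]] <- list(gene_id = sprintf("gene%04d", gi), chrom = chr,
                              strand = strand, start = start, end = end,
                              exons = ex, cds = cds)
    }
  }
  genes <- gene_models(
    gene_id = vapply(gene_rows, `[[`, "", "gene_id"),
    chrom = vapply(gene_rows, `[[`, "", "chrom"),
    strand = vapply(gene_rows, `[[`, "", "strand"),
    start = vapply(gene_rows, `[[`, numeric(1), "start"),
    end = vapply(gene_rows, `[[`, numeric(1), "end"),
    exons = lapply(gene_rows, `[[`, "exons"),
    cds = lapply(gene_rows, `[[`, "cds")
  )

  # conservation islands + low-score decoys
  n_islands <- round(config$island_frac * sum(sizes) / config$island_len)
  isl <- place_uniform(n_islands,
                       pmax(50, stats::rpois(n_islands, config$island_len)),
                       sizes)
  isl$score <- stats::runif(n_islands, config$island_score_range[1],
                            config$island_score_range[2])
  dec <- place_uniform(n_islands, pmax(50, stats::rpois(n_islands, 300)), sizes)
  dec$score <- stats::runif(n_islands, config$decoy_score_range[1],
                            config$decoy_score_range[2])
  track <- dplyr::bind_rows(isl, dec) |> dplyr::arrange(.data$chrom, .data$start)
  # drop runs overlapping an earlier run so the track stays disjoint
  keep <- rep(TRUE, nrow(track))
  last_end <- stats::setNames(rep(-1, length(sizes)), names(sizes))
  for (i in seq_len(nrow(track))) {
    if (track$start[i] < last_end[[track$chrom[i]]]) keep[i] <- FALSE
    else last_end[[track$chrom[i]]] <- track$end[i]
  }
  track <- as_conservation(track[keep, ])
  conserved <- call_conserved_regions(track)

  # annotation peaks
  peaks <- place_uniform(config$n_peaks, rep(config$peak_len, config$n_peaks),
                         sizes)
  peaks <- as_intervals(dplyr::mutate(
    peaks, name = sprintf("peak%05d", dplyr::row_number())))

  # background (conserved-region) overlap rate with the annotation
  q_b <- mean(overlaps_any(conserved, peaks))
  odds_e <- config$annotation_or * q_b / (1 - q_b)
  q_e <- odds_e / (1 + odds_e)

  islands_only <- as_intervals(isl[c("chrom", "start", "end")])
  elements <- list()
  for (cls in names(config$n_elements)) {
    n_el <- config$n_elements[[cls]]
    lens <- pmax(config$element_min_len,
                 round(stats::rlnorm(n_el, config$element_meanlog,
                                     config$element_sdlog)))
    in_peak <- stats::runif(n_el) < q_e
    rows <- vector("list", n_el)
    for (i in seq_len(n_el)) {
      if (in_peak[i]) {
        pk <- peaks[sample.int(nrow(peaks), 1), ]
        lo <- max(0, pk$start - lens[i] + 1)
        hi <- pk$end - 1
        start <- floor(stats::runif(1, lo, hi - lens[i] + 1))
        start <- max(0, min(start, sizes[[pk$chrom]] - lens[i]))
        rows[[i]] <- tibble::tibble(chrom = pk$chrom, start = start,
                                    end = start + lens[i])
      } else {
        for (try in 1:50) {
          if (stats::runif(1) < config$frac_on_islands) {
            il <- islands_only[sample.int(nrow(islands_only), 1), ]
            start <- floor(stats::runif(1, il$start,
                                        max(il$start + 1, il$end - lens[i])))
          } else {
            cand <- place_uniform(1, lens[i], sizes)
            start <- cand$start; il <- cand
          }
          start <- max(0, min(start, sizes[[il$chrom]] - lens[i]))
          cand_iv <- tibble::tibble(chrom = il$chrom, start = start,
                                    end = start + lens[i])
          if (!overlaps_any(cand_iv, peaks)) break
        }
        rows[[i]] <- cand_iv
      }
    }
    cls_el <- dplyr::bind_rows(rows)
    cls_el$name <- sprintf("%s-%05d", cls, seq_len(n_el))
    cls_el$class <- cls
    elements[[cls]] <- cls_el
  }
  elements <- as_intervals(dplyr::bind_rows(elements))

  truth <- list(annotation_or = config$annotation_or,
                element_peak_rate = q_e, background_peak_rate = q_b,
                n_islands = n_islands)
  list(genome = genome, chrom_sizes = sizes, genes = genes,
       conservation = track, conserved_regions = conserved,
       annotation = peaks, elements = elements, truth = truth)
}

#' Simulate a distance-decaying contact map with planted loops
#'
#' Background contacts at bin distance `d` are Weibull draws whose scale
#' follows a power-law decay `scale0 * d^(-alpha)` (in bin units) with a
#' configured dispersion shape; a distance-increasing fraction of entries
#' is zeroed to emulate sparsity. Planted element-to-promoter loops
#' multiply the Weibull scale (hence the mean) by `loop_fold` and are never
#' zeroed. Only the `window`-wide band around the diagonal is populated,
#' which covers every candidate the interaction caller can test.
#'
#' @param config A [synth_config()].
#' @param sim Output of [simulate_genome()] (uses `chrom_sizes`, `elements`,
#'   `genes`).
#' @return List with `contacts` (a `contact_matrix`) and `truth_loops`
#'   (tibble `element`, `gene_id`, `chrom`, `anchor`, `candidate`).
#' @export
simulate_contacts <- function(config, sim) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, 202))
  bs <- config$bin_size
  sizes <- sim$chrom_sizes
  n_bins <- ceiling(sizes / bs)
  if (any(n_bins < 200)) stop("need at least 200 bins per chromosome")
  max_off <- floor(config$window / bs) - 1

  trip <- list()
  for (chr in names(sizes)) {
    nb <- n_bins[[chr]]
    for (k in seq_len(max_off)) {
      i <- 0:(nb - 1 - k)
      lambda <- config$scale0 * k^(-config$decay_alpha)
      x <- stats::rweibull(length(i), shape = config$dispersion_shape,
                           scale = lambda)
      zp <- config$zero_prob_near +
        (config$zero_prob_far - config$zero_prob_near) * (k / max_off)
      x[stats::runif(length(i)) < zp] <- 0
      keep <- x > 0
      trip[[paste(chr, k)]] <- tibble::tibble(chrom = chr, bin1 = i[keep],
                                              bin2 = i[keep] + k, count = x[keep])
    }
  }
  trip <- dplyr::bind_rows(trip)

  # planted loops: element anchor bin <-> promoter-containing bin
  el <- sim$elements
  genes <- sim$genes
  prom <- promoter_regions(genes, 2000, sizes)
  prom$mid_bin <- floor((prom$start + prom$end) / 2 / bs)
  el$anchor <- floor(el$start / bs)
  loops <- list()
  used <- character(0)
  tries <- 0
  while (length(loops) < config$n_loops && tries < 50000) {
    tries <- tries + 1
    ei <- sample.int(nrow(el), 1)
    cand_prom <- prom[prom$chrom == el$chrom[ei], ]
    if (nrow(cand_prom) == 0) next
    off <- abs(cand_prom$mid_bin - el$anchor[ei])
    ok <- which(off >= 1 & off <= max_off)
    if (length(ok) == 0) next
    pi <- ok[sample.int(length(ok), 1)]
    key <- paste(el$chrom[ei], el$anchor[ei], cand_prom$mid_bin[pi])
    if (key %in% used || el$name[ei] %in% vapply(loops, `[[`, "", "element")) next
    used <- c(used, key)
    loops[[length(loops) + 1]] <- list(element = el$name[ei],
                                       gene_id = cand_prom$name[pi],
                                       chrom = el$chrom[ei],
                                       anchor = el$anchor[ei],
                                       candidate = cand_prom$mid_bin[pi])
  }
  if (length(loops) < config$n_loops) {
    stop("could not place the requested number of loops")
  }
  truth_loops <- tibble::tibble(
    element = vapply(loops, `[[`, "", "element"),
    gene_id = vapply(loops, `[[`, "", "gene_id"),
    chrom = vapply(loops, `[[`, "", "chrom"),
    anchor = vapply(loops, `[[`, numeric(1), "anchor"),
    candidate = vapply(loops, `[[`, numeric(1), "candidate")
  )
  loop_k <- abs(truth_loops$candidate - truth_loops$anchor)
  loop_scale <- config$scale0 * loop_k^(-config$decay_alpha) * config$loop_fold
  loop_val <- stats::rweibull(nrow(truth_loops),
                              shape = config$dispersion_shape,
                              scale = loop_scale)
  loop_trip <- tibble::tibble(chrom = truth_loops$chrom,
                              bin1 = pmin(truth_loops$anchor, truth_loops$candidate),
                              bin2 = pmax(truth_loops$anchor, truth_loops$candidate),
                              count = loop_val)
  trip <- trip |>
    dplyr::anti_join(loop_trip[c("chrom", "bin1", "bin2")],
                     by = c("chrom", "bin1", "bin2")) |>
    dplyr::bind_rows(loop_trip)
  list(contacts = contact_matrix(trip, bin_size = bs, chrom_sizes = sizes),
       truth_loops = truth_loops)
}

#' Simulate two-species expression atlases and comparative tables
#'
#' Builds smooth logistic-ramp trajectories shared between species, adds
#' stage noise, and plants: a gene set with a configured stage-matched
#' expression Z shift in human (centered within the row so only the
#' matched stages move); a breakpoint-difference shift; a marker gene set
#' with a fold change in one cell cluster; lower dN/dS for a planted set;
#' a prenatal-shifted set in the bulk atlas; and gene-set membership with
#' a configured odds ratio against a coding-length covariate background.
#'
#' @param config A [synth_config()].
#' @return List with `human_expr`, `other_expr` (gene x stage tibbles),
#'   `stage_pairs`, `bulk_expr`, `bulk_meta`, `bulk_sets`, `cells`,
#'   `clusters`, `breakpoints`, `dnds`, `geneset_annotation`, `modules`,
#'   `module_background`, `module_set` and `truth`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(derive_seed(config$seed, 303))
  n <- config$n_orthologs
  ids <- sprintf("ortho%05d", seq_len(n))
  hs <- config$human_scores
  os <- config$other_scores
  stopifnot(length(hs) >= 3, length(os) >= 3,
            all(config$matched_pairs$human_score %in% hs),
            all(config$matched_pairs$other_score %in% os))

  base <- stats::rnorm(n, 6, 1.5)
  # dynamic genes: trajectory amplitude bounded away from 0 so stage
  # Z-scores reflect developmental signal rather than pure noise
  amp <- sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, 1, 4)
  mid <- stats::runif(n, 0.2, 0.8)
  width <- stats::runif(n, 0.12, 0.3)
  latent <- function(scores) {
    t(vapply(seq_len(n), function(g) {
      base[g] + amp[g] * stats::plogis((scores - mid[g]) / width[g])
    }, numeric(length(scores))))
  }
  # Event scores are the cross-species developmental alignment scale, so
  # the other species' latent clock is warped onto the human scale through
  # the matched pairs: matched stages then represent the same
  # developmental state and differ only by noise (plus planted shifts).
  warp <- stats::approxfun(
    c(0, config$matched_pairs$other_score, 1),
    c(0, config$matched_pairs$human_score, 1), rule = 2)
  H <- latent(hs) + stats::rnorm(n * length(hs), 0, config$stage_noise_sd)
  O <- latent(warp(os)) + stats::rnorm(n * length(os), 0, config$stage_noise_sd)
  colnames(H) <- paste0("h", hs)
  colnames(O) <- paste0("m", os)
  rownames(H) <- rownames(O) <- ids

  dz_set <- sample(ids, config$deltaz_set_size)
  matched_cols <- paste0("h", config$matched_pairs$human_score)
  bump <- as.numeric(colnames(H) %in% matched_cols)
  bump <- bump - mean(bump)   # keep the row mean unchanged
  # Calibrate per-gene bump gains so that after row standardization the
  # matched stages move by exactly deltaz_shift Z units: adding the bump
  # also perturbs each row's mean/SD, so a fixed-point refinement is run
  # against the achieved Z displacement.
  H0 <- H[dz_set, , drop = FALSE]
  row_z <- function(m) (m - rowMeans(m)) / apply(m, 1, stats::sd)
  z0 <- row_z(H0)
  gain <- apply(H0, 1, stats::sd) * config$deltaz_shift /
    (1 - mean(colnames(H) %in% matched_cols))
  for (it in 1:3) {
    Hs <- H0 + outer(gain, bump)
    achieved <- rowMeans((row_z(Hs) - z0)[, matched_cols, drop = FALSE])
    gain <- gain * config$deltaz_shift / pmax(achieved, 1e-6)
  }
  H[dz_set, ] <- H0 + outer(gain, bump)
  stage_pairs <- tibble::tibble(
    human_score = config$matched_pairs$human_score,
    other_score = config$matched_pairs$other_score,
    human_stage = paste0("h", config$matched_pairs$human_score),
    other_stage = paste0("m", config$matched_pairs$other_score)
  )

  # breakpoint table
  bp_set <- sample(setdiff(ids, dz_set), config$breakpoint_set_size)
  bp_bg <- sample(setdiff(ids, c(dz_set, bp_set)),
                  min(config$breakpoint_background_size,
                      n - config$deltaz_set_size - config$breakpoint_set_size))
  breakpoints <- tibble::tibble(
    gene_id = c(bp_set, bp_bg),
    delta = c(stats::rnorm(length(bp_set), config$breakpoint_shift,
                           config$breakpoint_sd),
              stats::rnorm(length(bp_bg), 0, config$breakpoint_sd))
  )

  # dN/dS records
  dnds_set <- dz_set
  ratio <- ifelse(ids %in% dnds_set,
                  stats::rlnorm(n, log(config$dnds_set_median),
                                config$dnds_sdlog),
                  stats::rlnorm(n, log(config$dnds_background_median),
                                config$dnds_sdlog))
  dS <- stats::rlnorm(n, 0, 0.3)
  dnds <- tibble::tibble(gene_id = ids, dN = ratio * dS, dS = dS,
                         species_pair = "macaque")

  # bulk developmental atlas (prenatal / postnatal samples)
  npp <- config$n_bulk_samples_per_period
  bulk_samples <- c(sprintf("pre%03d", seq_len(npp)),
                    sprintf("post%03d", seq_len(npp)))
  period <- rep(c("prenatal", "postnatal"), each = npp)
  bulk_base <- matrix(stats::rlnorm(n * 2 * npp, 3, 1), nrow = n,
                      dimnames = list(ids, bulk_samples))
  pre_set <- sample(setdiff(ids, dz_set), config$bulk_set_size)
  neutral_set <- sample(setdiff(ids, c(dz_set, pre_set)), config$bulk_set_size)
  # +1 SD (on the log2 scale) prenatal shift for the planted set
  bulk_log <- log2(bulk_base + 1)
  sdlog <- stats::sd(as.numeric(bulk_log))
  bulk_log[pre_set, period == "prenatal"] <-
    bulk_log[pre_set, period == "prenatal"] + config$bulk_shift_sd * sdlog
  bulk_expr <- matrix_to_expr(2^bulk_log - 1)
  bulk_meta <- tibble::tibble(sample = bulk_samples, period = period,
                              stage = period, age = seq_along(bulk_samples))
  bulk_sets <- list(prenatal_high = pre_set, neutral = neutral_set)

  # single cells with one planted marker cluster
  clusters_lab <- paste0("cluster", seq_len(config$n_clusters))
  cell_ids <- sprintf("cell%04d", seq_len(config$n_clusters *
                                            config$cells_per_cluster))
  cell_cluster <- rep(clusters_lab, each = config$cells_per_cluster)
  cg <- sprintf("cgene%04d", seq_len(config$n_cell_genes))
  cells_m <- matrix(stats::rnorm(config$n_cell_genes * length(cell_ids), 2, 1),
                    nrow = config$n_cell_genes,
                    dimnames = list(cg, cell_ids))
  markers <- sample(cg, config$marker_set_size)
  cells_m[markers, cell_cluster == config$marker_cluster] <-
    cells_m[markers, cell_cluster == config$marker_cluster] +
    log2(config$marker_fold)
  clusters <- tibble::tibble(cell = cell_ids, cluster = cell_cluster)

  # gene-set annotation with coding-length covariate and planted OR
  bg_ids <- sprintf("bg%05d", seq_len(config$n_background_genes))
  target <- as.integer(seq_len(config$n_background_genes) <=
                         config$n_target_genes)
  target <- sample(target)
  p0 <- config$geneset_base_rate
  odds1 <- config$geneset_or * p0 / (1 - p0)
  p1 <- odds1 / (1 + odds1)
  in_set <- stats::rbinom(config$n_background_genes, 1,
                          ifelse(target == 1, p1, p0))
  cds_len <- round(stats::rlnorm(config$n_background_genes, log(1500), 0.8))
  geneset_annotation <- tibble::tibble(gene_id = bg_ids, target = target,
                                       in_set = in_set, cds_length = cds_len)

  # modules: one planted at module_or, the rest neutral
  module_set <- sample(bg_ids, config$n_target_genes)
  mod_names <- sprintf("M%03d", seq_len(config$n_modules))
  planted_mod <- mod_names[1]
  q0 <- config$module_size / config$n_background_genes
  oddsm <- config$module_or * q0 / (1 - q0)
  q1 <- oddsm / (1 + oddsm)
  modules <- dplyr::bind_rows(lapply(mod_names, function(mn) {
    if (mn == planted_mod) {
      pr <- ifelse(bg_ids %in% module_set, q1, q0)
      memb <- bg_ids[stats::runif(length(bg_ids)) < pr]
    } else {
      memb <- sample(bg_ids, config$module_size)
    }
    tibble::tibble(gene_id = memb, module = mn)
  }))

  truth <- list(deltaz_genes = dz_set, deltaz_shift = config$deltaz_shift,
                breakpoint_genes = bp_set, breakpoint_background = bp_bg,
                breakpoint_shift = config$breakpoint_shift,
                dnds_genes = dnds_set,
                prenatal_high_genes = pre_set,
                marker_genes = markers, marker_cluster = config$marker_cluster,
                geneset_or = config$geneset_or,
                planted_module = planted_mod, module_or = config$module_or,
                module_set = module_set)
  list(human_expr = matrix_to_expr(H), other_expr = matrix_to_expr(O),
       stage_pairs = stage_pairs, bulk_expr = bulk_expr,
       bulk_meta = bulk_meta, bulk_sets = bulk_sets,
       cells = matrix_to_expr(cells_m), clusters = clusters,
       breakpoints = breakpoints, dnds = dnds,
       geneset_annotation = geneset_annotation, modules = modules,
       module_background = bg_ids, module_set = module_set, truth = truth)
}
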