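#' Maximum-likelihood fit of a two-parameter Weibull
#'
#' Profile-likelihood estimator: the shape solves
#' `sum(x^k log x)/sum(x^k) - 1/k - mean(log x) = 0` (monotone in `k`),
#' and the scale is `(mean(x^k))^(1/k)`. Observations are rescaled by their
#' mean before solving for numerical stability.
#'
#' @param x Strictly positive observations (length >= 2, non-constant).
#' @return Named numeric vector `c(shape, scale)`.
#' @export
weibull_mle <- function(x) {
  if (length(x) < 2) stop("need at least 2 observations")
  if (any(x <= 0)) stop("Weibull fit requires strictly positive values")
  if (stats::sd(x) == 0) stop("degenerate fit: all observations identical")
  m <- mean(x)
  y <- x / m
  ly <- log(y)
  mly <- mean(ly)
  g <- function(k) {
    w <- y^k
    sum(w * ly) / sum(w) - 1 / k - mly
  }
  lo <- 0.01; hi <- 1
  while (g(hi) < 0 && hi < 1e4) hi <- hi * 2
  k <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
  lambda <- m * mean(y^k)^(1 / k)
  c(shape = k, scale = lambda)
}

#' Fit the per-(chromosome, distance) Weibull contact null
#'
#' Fits a two-parameter Weibull by maximum likelihood to the strictly
#' positive background contacts in every (chromosome, distance) cell.
#' Cells with fewer than `min_obs` positive observations are pooled with
#' their nearest distance cells on the same chromosome (symmetrically
#' expanding) until the minimum is reached; pooled cells are flagged. The
#' zero fraction of each cell is recorded but zeros never enter the fit
#' (zero contacts receive p = 1 at call time).
#'
#' @param background_profiles Profile tibble from [locus_profiles()] run on
#'   matched-background anchors (columns `chrom`, `distance`, `contact`).
#' @param min_obs Minimum positive observations per fitted cell (default 30).
#' @return A `contact_null` object: tibble with `chrom`, `distance`,
#'   `shape`, `scale`, `n_obs`, `n_zero`, `zero_frac`, `pooled`.
#' @export
fit_contact_null <- function(background_profiles, min_obs = 30) {
  stopifnot(all(c("chrom", "distance", "contact") %in% names(background_profiles)))
  df <- tibble::as_tibble(background_profiles)
  rows <- list()
  for (chr in unique(df$chrom)) {
    sub <- df[df$chrom == chr, ]
    dists <- sort(unique(sub$distance))
    pos_by_d <- lapply(dists, function(d) {
      x <- sub$contact[sub$distance == d]
      x[x > 0]
    })
    n_by_d <- vapply(split(sub$contact, factor(sub$distance, levels = dists)),
                     length, integer(1))
    for (di in seq_along(dists)) {
      x <- pos_by_d[[di]]
      pooled <- FALSE
      r <- 1
      while (length(x) < min_obs && r < length(dists)) {
        pooled <- TRUE
        nb <- c(di - r, di + r)
        nb <- nb[nb >= 1 & nb <= length(dists)]
        x <- c(x, unlist(pos_by_d[nb]))
        r <- r + 1
      }
      if (length(x) == 0) {
        stop("no positive contacts for cell (", chr, ", ", dists[di],
             ") even after pooling")
      }
      fit <- weibull_mle(x)
      n_cell <- n_by_d[[di]]
      n_zero <- n_cell - length(pos_by_d[[di]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        chrom = chr, distance = dists[di],
        shape = fit[["shape"]], scale = fit[["scale"]],
        n_obs = length(x), n_zero = n_zero,
        zero_frac = n_zero / n_cell, pooled = pooled
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("contact_null", class(out))
  out
}

#' @export
print.contact_null <- function(x, ...) {
  cat("Weibull contact null:", nrow(x), "(chromosome, distance) cells,",
      sum(x$pooled), "pooled\n")
  NextMethod()
}

#' @method tidy contact_null
#' @export
tidy.contact_null <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "contact_null")
  out
}

#' @method glance contact_null
#' @export
glance.contact_null <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x), n_pooled = sum(x$pooled),
                 median_shape = stats::median(x$shape),
                 mean_zero_frac = mean(x$zero_frac))
}

#' Weibull survival p-values for locus profiles
#'
#' For a positive contact `x` in a cell with fitted parameters
#' (shape, scale) the p-value is the survival probability
#' `exp(-(x/scale)^shape)`; zero contacts get p = 1.
#'
#' @param profiles Profile tibble from [locus_profiles()].
#' @param null A `contact_null` from [fit_contact_null()].
#' @return `profiles` with an added `p` column.
#' @export
interaction_pvalues <- function(profiles, null) {
  stopifnot(inherits(null, "contact_null"))
  joined <- dplyr::left_join(tibble::as_tibble(profiles),
                             tibble::as_tibble(null)[c("chrom", "distance",
                                                       "shape", "scale")],
                             by = c("chrom", "distance"))
  if (anyNA(joined$shape)) {
    miss <- dplyr::distinct(joined[is.na(joined$shape), c("chrom", "distance")])
    stop("null model does not cover ", nrow(miss), " (chromosome, distance) ",
         "cell(s), e.g. (", miss$chrom[1], ", ", miss$distance[1], ")")
  }
  joined$p <- ifelse(joined$contact > 0,
                     exp(-(joined$contact / joined$scale)^joined$shape), 1)
  dplyr::select(joined, -"shape", -"scale")
}

#' Benjamini-Hochberg correction and significance calls
#'
#' Adjusts p-values across the full family of element x candidate-bin
#' tests and marks calls with `q < fdr` significant.
#'
#' @param calls Tibble with a `p` column (from [interaction_pvalues()]).
#' @param fdr FDR threshold (default 0.01).
#' @return `calls` with added `q` and `significant` columns.
#' @export
correct_and_call <- function(calls, fdr = 0.01) {
  stopifnot(nrow(calls) > 0, "p" %in% names(calls))
  calls <- tibble::as_tibble(calls)
  calls$q <- stats::p.adjust(calls$p, method = "BH")
  calls$significant <- calls$q < fdr
  calls
}

# Draw one simulated contact per profile row from the fitted null,
# preserving each cell's zero fraction when requested.
simulate_null_contacts <- function(profiles, null, keep_zero_frac = FALSE) {
  joined <- dplyr::left_join(tibble::as_tibble(profiles),
                             tibble::as_tibble(null)[c("chrom", "distance",
                                                       "shape", "scale",
                                                       "zero_frac")],
                             by = c("chrom", "distance"))
  stopifnot(!anyNA(joined$shape))
  x <- stats::rweibull(nrow(joined), shape = joined$shape, scale = joined$scale)
  if (keep_zero_frac) {
    x[stats::runif(nrow(joined)) < joined$zero_frac] <- 0
  }
  joined$contact <- x
  dplyr::select(joined, -"shape", -"scale", -"zero_frac")
}
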