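# maximum-likelihood fits of the three stromule measurement distributions
# and derived quantities (stromule frequency, density-derived separations)

# pull a numeric column out of a data frame, or pass a vector through
resolve_column <- function(x, column) {
  if (is.data.frame(x)) {
    if (!column %in% names(x)) {
      abort(sprintf("Data frame input must have a `%s` column.", column))
    }
    x[[column]]
  } else {
    as.numeric(x)
  }
}

#' Fit a Poisson model to per-plastid stromule counts
#'
#' Stromule initiation events per plastid are modeled as independent with a
#' characteristic rate, so counts follow a Poisson distribution. The MLE of
#' the rate is the sample mean; the implied stromule frequency (proportion of
#' plastids with at least one stromule) is `1 - exp(-lambda)`. Goodness of
#' fit is a chi-square test on count categories with the tail pooled so every
#' expected count is at least 5 (df = categories - 2, one parameter
#' estimated).
#'
#' @param counts Non-negative integer vector, or a data frame with a
#'   `stromule_count` column (e.g. the plastid table from
#'   [generate_stromule_table()]).
#' @return A `<poisson_fit>` with fields `lambda`, `se`, `n`, `implied_sf`,
#'   `gof_statistic`, `gof_df`, `gof_p`. Use [tidy()]/[glance()] for tibble
#'   views.
#' @examples
#' fit_poisson_counts(c(0, 1, 2))  # lambda = 1
#' @export
fit_poisson_counts <- function(counts) {
  counts <- resolve_column(counts, "stromule_count")
  if (length(counts) == 0L) abort("`counts` must be non-empty.")
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-8)) {
    abort("`counts` must be non-negative integers.")
  }
  counts <- round(counts)
  n <- length(counts)
  lambda <- mean(counts)
  gof <- poisson_gof(counts, lambda)
  structure(
    list(
      lambda = lambda,
      se = sqrt(lambda / n),
      n = n,
      implied_sf = 1 - exp(-lambda),
      gof_statistic = gof$statistic,
      gof_df = gof$df,
      gof_p = gof$p.value,
      gof_method = "chi-square, tail pooled to expected >= 5"
    ),
    class = c("poisson_fit", "stromule_fit")
  )
}

# chi-square GOF for Poisson counts; categories 0..K-1 and a pooled >=K tail,
# K chosen as the largest cut with every expected count >= 5
poisson_gof <- function(counts, lambda) {
  n <- length(counts)
  if (lambda <= 0 || n < 10) {
    return(list(statistic = NA_real_, df = NA_real_, p.value = NA_real_))
  }
  kmax <- max(counts)
  for (K in seq(kmax + 1, 1)) {
    expected <- c(n * dpois(0:(K - 1), lambda), n * (1 - stats::ppois(K - 1, lambda)))
    if (all(expected >= 5)) break
  }
  if (K < 2) {
    return(list(statistic = NA_real_, df = NA_real_, p.value = NA_real_))
  }
  obs_cat <- pmin(counts, K)
  observed <- vapply(0:K, function(k) sum(obs_cat == k), numeric(1))
  stat <- sum((observed - expected)^2 / expected)
  df <- (K + 1) - 2 # one parameter estimated from the data
  list(statistic = stat, df = df,
       p.value = if (df >= 1) pchisq(stat, df, lower.tail = FALSE) else NA_real_)
}

#' Fit a log-normal model to stromule lengths
#'
#' Stromule lengths are well described by a log-normal distribution (the
#' signature of growth by independent multiplicative increments). The MLEs
#' are the mean and population standard deviation of the log lengths; the
#' distributional median and quartiles are `exp(mu)` and
#' `exp(mu -/+ z0.75 * sigma)` with `z0.75 = qnorm(0.75)`, so the geometric
#' mean of the fitted quartiles equals the fitted median by construction.
#' Sample quartiles (linear-interpolation convention) are reported alongside.
#' Goodness of fit is a Kolmogorov-Smirnov test against the fitted
#' distribution.
#'
#' @param lengths Positive numeric vector of lengths in µm, or a data frame
#'   with a `length_um` column (e.g. the lengths table from
#'   [generate_stromule_table()]).
#' @return A `<lognormal_fit>` with fields `mu`, `sigma`, `n`, `median`,
#'   `q1`, `q3`, `sample_median`, `sample_q1`, `sample_q3`, `gof_statistic`,
#'   `gof_p`.
#' @export
fit_lognormal_lengths <- function(lengths) {
  lengths <- resolve_column(lengths, "length_um")
  if (length(lengths) < 2L) abort("`lengths` needs at least 2 observations.")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    abort("`lengths` must be positive (µm).")
  }
  logl <- log(lengths)
  mu <- mean(logl)
  sigma <- sqrt(mean((logl - mu)^2)) # MLE (population) standard deviation
  z <- qnorm(0.75)
  ks <- if (sigma > 0) {
    suppressWarnings(ks.test(lengths, "plnorm", meanlog = mu, sdlog = sigma))
  } else {
    NULL
  }
  sq <- quantile(lengths, c(0.25, 0.5, 0.75), names = FALSE)
  structure(
    list(
      mu = mu,
      sigma = sigma,
      n = length(lengths),
      median = exp(mu),
      q1 = exp(mu - z * sigma),
      q3 = exp(mu + z * sigma),
      sample_median = sq[2],
      sample_q1 = sq[1],
      sample_q3 = sq[3],
      gof_statistic = if (is.null(ks)) NA_real_ else unname(ks$statistic),
      gof_p = if (is.null(ks)) NA_real_ else ks$p.value,
      gof_method = "Kolmogorov-Smirnov vs fitted log-normal"
    ),
    class = c("lognormal_fit", "stromule_fit")
  )
}

#' Fit a power law to plastid density versus cell area
#'
#' Plastid density (plastids per µm² of cell area) decays with cell area
#' toward an asymptotic packing density. The model `density = a * area^b` is
#' fitted by ordinary least squares of `log(density)` on `log(area)` — the
#' scale on which the model is linear and on which R² is reported (the
#' limited multiplicative range of real cell areas means the power law should
#' be read as an empirical summary, not a mechanistic claim).
#'
#' @param cells A data frame with columns `area_um2` and `plastid_count`
#'   (e.g. from [generate_cell_table()]), or a numeric vector of cell areas.
#' @param plastid_counts Positive integer counts per cell; required when
#'   `cells` is a vector.
#' @return A `<powerlaw_fit>` with fields `a` (density at unit area, µm^-2),
#'   `b` (exponent), `b_se`, `r_squared`, `n`.
#' @export
fit_powerlaw_density <- function(cells, plastid_counts = NULL) {
  if (is.data.frame(cells)) {
    areas <- resolve_column(cells, "area_um2")
    counts <- resolve_column(cells, "plastid_count")
  } else {
    areas <- as.numeric(cells)
    counts <- as.numeric(plastid_counts)
  }
  if (length(areas) < 3L) abort("Need at least 3 cells.")
  if (length(areas) != length(counts)) {
    abort("`areas` and `counts` must have equal length.")
  }
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    abort("Cell areas must be positive (µm²).")
  }
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    abort("Plastid counts must be positive.")
  }
  density <- counts / areas
  fit <- lm(log(density) ~ log(areas))
  sm <- summary(fit)
  structure(
    list(
      a = exp(unname(coef(fit)[1])),
      b = unname(coef(fit)[2]),
      b_se = unname(sm$coefficients[2, 2]),
      r_squared = sm$r.squared,
      n = length(areas)
    ),
    class = c("powerlaw_fit", "stromule_fit")
  )
}

#' Stromule frequency of a plastid population
#'
#' Proportion of plastids bearing at least one stromule (SF%, reported as a
#' proportion in `[0, 1]`).
#'
#' @inheritParams fit_poisson_counts
#' @return A proportion.
#' @examples
#' stromule_frequency(c(0, 0, 1, 2)) # 0.5
#' @export
stromule_frequency <- function(counts) {
  counts <- resolve_column(counts, "stromule_count")
  if (length(counts) == 0L) abort("`counts` must be non-empty.")
  mean(counts >= 1)
}

#' Characteristic plastid separation implied by a density
#'
#' Interpreting a plastid density as one plastid per square "box" of
#' cytoplasm, the characteristic plastid-plastid separation is the box side
#' length `1 / sqrt(density)`. Measured densities of 0.014 µm^-2 (small
#' cells) down to 0.004 µm^-2 (large-cell asymptote) correspond to
#' separations of roughly 8.5-15.8 µm.
#'
#' @param density Plastid density in µm^-2 (> 0); vectorized.
#' @return Separation(s) in µm.
#' @examples
#' density_to_separation(c(0.014, 0.004))
#' @export
density_to_separation <- function(density) {
  if (any(!is.finite(density)) || any(density <= 0)) {
    abort("`density` must be positive (µm^-2).")
  }
  1 / sqrt(density)
}
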