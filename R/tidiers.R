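# broom-style tidiers for the fitted distribution objects

#' Tidy and glance methods for stromule distribution fits
#'
#' `tidy()` returns one row per fitted parameter (columns `term`, `estimate`
#' and, where available, `std.error`); `glance()` returns a one-row summary
#' with sample size, derived quantities and goodness-of-fit columns.
#'
#' @param x A `<poisson_fit>`, `<lognormal_fit>` or `<powerlaw_fit>`.
#' @param ... Unused.
#' @return A tibble.
#' @name fit_tidiers
NULL

#' @rdname fit_tidiers
#' @method tidy poisson_fit
#' @export
tidy.poisson_fit <- function(x, ...) {
  tibble(term = "lambda", estimate = x$lambda, std.error = x$se)
}

#' @rdname fit_tidiers
#' @method glance poisson_fit
#' @export
glance.poisson_fit <- function(x, ...) {
  tibble(
    n = x$n, lambda = x$lambda, implied_sf = x$implied_sf,
    statistic = x$gof_statistic, df = x$gof_df, p.value = x$gof_p
  )
}

#' @rdname fit_tidiers
#' @method tidy lognormal_fit
#' @export
tidy.lognormal_fit <- function(x, ...) {
  tibble(
    term = c("mu", "sigma"),
    estimate = c(x$mu, x$sigma),
    std.error = c(x$sigma / sqrt(x$n), x$sigma / sqrt(2 * x$n))
  )
}

#' @rdname fit_tidiers
#' @method glance lognormal_fit
#' @export
glance.lognormal_fit <- function(x, ...) {
  tibble(
    n = x$n, median = x$median, q1 = x$q1, q3 = x$q3,
    sample_median = x$sample_median,
    statistic = x$gof_statistic, p.value = x$gof_p
  )
}

#' @rdname fit_tidiers
#' @method tidy powerlaw_fit
#' @export
tidy.powerlaw_fit <- function(x, ...) {
  tibble(
    term = c("a", "b"),
    estimate = c(x$a, x$b),
    std.error = c(NA_real_, x$b_se)
  )
}

#' @rdname fit_tidiers
#' @method glance powerlaw_fit
#' @export
glance.powerlaw_fit <- function(x, ...) {
  tibble(n = x$n, a = x$a, b = x$b, r.squared = x$r_squared)
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat(sprintf(
    "<poisson_fit> lambda = %.4f (se %.4f), n = %d, implied SF = %.1f%%\n",
    x$lambda, x$se, x$n, 100 * x$implied_sf
  ))
  if (is.finite(x$gof_p)) {
    cat(sprintf("  GOF %s: X² = %.2f, df = %d, p = %.3g\n",
                x$gof_method, x$gof_statistic, x$gof_df, x$gof_p))
  }
  invisible(x)
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf(
    "<lognormal_fit> mu = %.4f, sigma = %.4f, n = %d\n  median %.2f µm (fitted quartiles %.2f, %.2f µm)\n",
    x$mu, x$sigma, x$n, x$median, x$q1, x$q3
  ))
  if (is.finite(x$gof_p)) {
    cat(sprintf("  GOF %s: D = %.4f, p = %.3g\n",
                x$gof_method, x$gof_statistic, x$gof_p))
  }
  invisible(x)
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "<powerlaw_fit> density = %.4g * area^%.3f, R² = %.3f (log-log), n = %d\n",
    x$a, x$b, x$r_squared, x$n
  ))
  invisible(x)
}
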