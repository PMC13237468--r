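#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a first-stage probit fit
#'
#' One row per coefficient with robust standard errors and normal confidence
#' bounds.
#'
#' @param x A `probit_fit`.
#' @param conf_level Confidence level.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `statistic`,
#'   `p_value`, `conf_low`, `conf_high`.
#' @export
tidy.probit_fit <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(x$coefficients), estimate = unname(x$coefficients),
    std_error = unname(se), statistic = unname(z),
    p_value = 2 * stats::pnorm(-abs(unname(z))),
    conf_low = unname(x$coefficients - q * se),
    conf_high = unname(x$coefficients + q * se)
  )
}

#' @rdname tidy.probit_fit
#' @export
glance.probit_fit <- function(x, ...) {
  tibble::tibble(n = x$n, loglik = x$loglik, converged = x$converged,
                 n_iter = x$n_iter, n_coef = length(x$coefficients))
}

#' Tidy a second-stage count/OLS fit
#'
#' One row per coefficient. The bootstrap covariance is used when attached
#' (i.e. when the fit came out of [fit_cf_2sri()]), otherwise the naive robust
#' one; log-link families also report the percentage-change transform of each
#' coefficient.
#'
#' @param x A `count_fit`.
#' @param conf_level Confidence level.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.count_fit <- function(x, conf_level = 0.95, ...) {
  vc <- x$vcov_bootstrap %||% x$vcov_naive
  se <- sqrt(diag(vc))
  z <- x$coefficients / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    term = names(x$coefficients), estimate = unname(x$coefficients),
    std_error = unname(se), statistic = unname(z),
    p_value = 2 * stats::pnorm(-abs(unname(z))),
    conf_low = unname(x$coefficients - q * se),
    conf_high = unname(x$coefficients + q * se)
  )
  if (x$family %in% c("poisson", "negbin2")) {
    out$irr_percent <- irr_percent(out$estimate)
  }
  out
}

#' @rdname tidy.count_fit
#' @export
glance.count_fit <- function(x, ...) {
  tibble::tibble(n = x$n, family = x$family, loglik = x$loglik,
                 nb_alpha = x$nb_alpha %||% NA_real_,
                 n_boot = if (!is.null(x$boot)) x$boot$n_boot else 0L)
}

#' Tidy a two-stage control-function fit
#'
#' Second-stage coefficients with bootstrap inference when available;
#' `stage = "first"` returns the first-stage probit instead.
#'
#' @param x A `cf_2sri_fit`.
#' @param stage `"second"` (default) or `"first"`.
#' @param conf_level Confidence level.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.cf_2sri_fit <- function(x, stage = c("second", "first"),
                             conf_level = 0.95, ...) {
  stage <- match.arg(stage)
  if (stage == "first") return(tidy(x$first_stage, conf_level = conf_level))
  tidy(x$second_stage, conf_level = conf_level)
}

#' @rdname tidy.cf_2sri_fit
#' @export
glance.cf_2sri_fit <- function(x, ...) {
  et <- endogeneity_test(x)
  tibble::tibble(
    n = x$n, family = x$family,
    gamma = unname(x$second_stage$coefficients[x$roles$exposure]),
    delta = et$estimate, endogeneity_z = et$z, endogeneity_p = et$p_value,
    first_stage_loglik = x$first_stage$loglik,
    second_stage_loglik = x$second_stage$loglik,
    n_boot = if (!is.null(x$boot)) x$boot$n_boot else 0L
  )
}

#' Tidy a linear 2SLS fit
#'
#' @param x An `iv_fit`.
#' @param conf_level Confidence level.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.iv_fit <- function(x, conf_level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  q <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    term = names(x$coefficients), estimate = unname(x$coefficients),
    std_error = unname(se), statistic = unname(z),
    p_value = 2 * stats::pnorm(-abs(unname(z))),
    conf_low = unname(x$coefficients - q * se),
    conf_high = unname(x$coefficients + q * se)
  )
}

#' Tidy an instrument-diagnostics report
#'
#' One row per diagnostic statistic.
#'
#' @param x An `iv_diagnostics`.
#' @param ... Unused.
#' @return A tibble with `diagnostic`, `statistic`, `df`, `p_value`.
#' @export
tidy.iv_diagnostics <- function(x, ...) {
  rows <- list(
    tibble::tibble(diagnostic = "kp_rk_lm", statistic = x$kp_lm$statistic,
                   df = x$kp_lm$df, p_value = x$kp_lm$p_value),
    tibble::tibble(diagnostic = "kp_rk_wald_f", statistic = x$kp_wald_f,
                   df = NA_integer_, p_value = NA_real_),
    tibble::tibble(diagnostic = "cragg_donald_f", statistic = x$cragg_donald_f,
                   df = NA_integer_, p_value = NA_real_),
    tibble::tibble(diagnostic = "hansen_j", statistic = x$hansen_j$statistic,
                   df = x$hansen_j$df, p_value = x$hansen_j$p_value),
    tibble::tibble(diagnostic = "stock_yogo_10pct_bias",
                   statistic = x$stock_yogo_10pct_bias, df = NA_integer_,
                   p_value = NA_real_)
  )
  if (!is.null(x$endogeneity)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      diagnostic = "endogeneity_z", statistic = x$endogeneity$z,
      df = NA_integer_, p_value = x$endogeneity$p_value)
  }
  dplyr::bind_rows(rows)
}
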