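# ---- second-stage estimators -------------------------------------------------

# Build the second-stage model frame: controls + exposure (+ generalized
# residual when present in `extra`).
second_stage_design <- function(data, roles, extra = character(0)) {
  vars <- c(roles$controls, roles$exposure, extra)
  X <- build_design(data, vars, roles)
  assert_full_rank(X, "the second-stage model")
  X
}

check_count_outcome <- function(y, what) {
  if (anyNA(y)) stop(what, " contains missing values", call. = FALSE)
  if (any(y < 0) || any(y != round(y))) {
    stop(what, " must be a non-negative integer count", call. = FALSE)
  }
  invisible(TRUE)
}

new_count_fit <- function(coefficients, vcov_naive, family, loglik, fitted,
                          n, roles, extra, nb_alpha = NULL,
                          equidispersion = NULL, vcov_bootstrap = NULL,
                          boot = NULL) {
  structure(
    list(coefficients = coefficients, vcov_naive = vcov_naive,
         vcov_bootstrap = vcov_bootstrap, boot = boot, family = family,
         nb_alpha = nb_alpha, equidispersion = equidispersion,
         loglik = loglik, fitted = fitted, n = n, roles = roles,
         extra = extra),
    class = "count_fit"
  )
}

#' Poisson second stage
#'
#' Log-link Poisson MLE of the count outcome on the exogenous controls, the
#' exposure, and (when `residual` is supplied) the generalized residual from
#' the first stage. The reported `vcov_naive` is the heteroskedasticity-robust
#' sandwich covariance of the single-stage fit; it does not account for the
#' generated regressor -- use the bootstrap covariance from [fit_cf_2sri()]
#' for inference on two-step estimates.
#'
#' @param data Analysis table.
#' @param roles A [cf_roles()] declaration.
#' @param residual Optional numeric vector of generalized residuals to include
#'   (internally named `gen_resid`).
#' @param outcome Optional outcome column overriding `roles$outcome`.
#' @return An object of class `count_fit`.
#' @export
fit_poisson <- function(data, roles, residual = NULL, outcome = NULL) {
  outcome <- outcome %||% roles$outcome
  y <- data[[outcome]]
  check_count_outcome(y, paste0("outcome '", outcome, "'"))
  extra <- character(0)
  if (!is.null(residual) && any(residual != 0)) {
    data$gen_resid <- residual
    extra <- "gen_resid"
  }
  X <- second_stage_design(data, roles, extra)
  g <- stats::glm.fit(X, y, family = stats::poisson(),
                      control = list(epsilon = 1e-12, maxit = 100))
  if (!g$converged) warning("Poisson second stage did not converge",
                            call. = FALSE)
  co <- stats::setNames(g$coefficients, colnames(X))
  mu <- drop(g$fitted.values)
  # sandwich: A = (X' diag(mu) X)^{-1}, meat = X' diag((y-mu)^2) X
  A <- solve(crossprod(X * sqrt(mu)))
  meat <- crossprod(X * (y - mu))
  vc <- A %*% meat %*% A * length(y) / (length(y) - ncol(X))
  dimnames(vc) <- list(colnames(X), colnames(X))
  ll <- sum(stats::dpois(y, mu, log = TRUE))
  new_count_fit(co, vc, "poisson", ll, mu, length(y), roles, extra)
}

#' Negative-binomial (NB2) second stage
#'
#' NB2 MLE with conditional variance \eqn{\mu + \alpha\mu^2}; the
#' overdispersion parameter \eqn{\alpha} (the reciprocal of the `theta` of
#' [MASS::glm.nb()]) may sit at the Poisson boundary \eqn{\alpha = 0}. A
#' boundary-corrected likelihood-ratio equidispersion check against the
#' Poisson fit is reported (the null distribution is an equal mixture of a
#' point mass at zero and chi-square with one degree of freedom).
#'
#' @inheritParams fit_poisson
#' @return A `count_fit` with `family = "negbin2"`, `nb_alpha`, and an
#'   `equidispersion` list (LR statistic and boundary-corrected p-value).
#' @export
fit_negbin <- function(data, roles, residual = NULL, outcome = NULL) {
  outcome <- outcome %||% roles$outcome
  y <- data[[outcome]]
  check_count_outcome(y, paste0("outcome '", outcome, "'"))
  extra <- character(0)
  if (!is.null(residual) && any(residual != 0)) {
    data$gen_resid <- residual
    extra <- "gen_resid"
  }
  X <- second_stage_design(data, roles, extra)
  df <- as.data.frame(X[, -1L, drop = FALSE], check.names = FALSE)
  df$.y <- y
  pois <- fit_poisson(data, roles,
                      residual = if (length(extra)) data$gen_resid else NULL,
                      outcome = outcome)
  # the dispersion MLE can sit at the Poisson boundary (alpha = 0), where the
  # theta iteration diverges; treat that as the boundary solution
  nb <- tryCatch(
    suppressWarnings(MASS::glm.nb(.y ~ ., data = df,
                                  control = stats::glm.control(maxit = 200))),
    error = function(e) NULL
  )
  if (is.null(nb) || nb$theta > 1e8) {
    lr <- 0
    return(new_count_fit(pois$coefficients, pois$vcov_naive, "negbin2",
                         pois$loglik, pois$fitted, length(y), roles, extra,
                         nb_alpha = 0,
                         equidispersion = list(lr = lr, p_value = 0.5)))
  }
  co <- stats::setNames(stats::coef(nb), colnames(X))
  mu <- stats::fitted(nb)
  alpha <- 1 / nb$theta
  vc <- sandwich::sandwich(nb)
  dimnames(vc) <- list(colnames(X), colnames(X))
  lr <- max(0, 2 * (as.numeric(stats::logLik(nb)) - pois$loglik))
  p_boundary <- 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  new_count_fit(co, vc, "negbin2", as.numeric(stats::logLik(nb)), mu,
                length(y), roles, extra, nb_alpha = alpha,
                equidispersion = list(lr = lr, p_value = p_boundary))
}

#' Least-squares second stage (placebo outcome)
#'
#' Ordinary least squares with heteroskedasticity-robust (HC1) standard
#' errors; used by the placebo harness where the outcome is continuous
#' (household-head age) rather than a count.
#'
#' @inheritParams fit_poisson
#' @return A `count_fit` with `family = "ols"`.
#' @export
fit_ols <- function(data, roles, residual = NULL, outcome = NULL) {
  outcome <- outcome %||% roles$outcome
  y <- data[[outcome]]
  if (anyNA(y)) stop("outcome contains missing values", call. = FALSE)
  extra <- character(0)
  if (!is.null(residual) && any(residual != 0)) {
    data$gen_resid <- residual
    extra <- "gen_resid"
  }
  X <- second_stage_design(data, roles, extra)
  fit <- stats::lm.fit(X, y)
  co <- stats::setNames(fit$coefficients, colnames(X))
  e <- drop(fit$residuals)
  A <- solve(crossprod(X))
  meat <- crossprod(X * e)
  vc <- A %*% meat %*% A * length(y) / (length(y) - ncol(X))
  dimnames(vc) <- list(colnames(X), colnames(X))
  sigma2 <- sum(e^2) / (length(y) - ncol(X))
  ll <- -0.5 * length(y) * (log(2 * pi * sigma2) + 1)
  new_count_fit(co, vc, "ols", ll, drop(X %*% fit$coefficients),
                length(y), roles, extra)
}

#' Percentage change implied by a log-link coefficient
#'
#' The incidence-rate-ratio transform: a Poisson log-link coefficient
#' \eqn{\beta} corresponds to a \eqn{(e^{\beta} - 1)\times 100} percent change
#' in the conditional mean. Reports tabulate this to one decimal place.
#'
#' @param coef Numeric vector of coefficients.
#' @return Numeric vector of percentage changes.
#' @examples
#' irr_percent(0.044) # 4.498... -> prints as 4.5
#' irr_percent(log(2)) # exactly 100
#' @export
irr_percent <- function(coef) {
  stopifnot(is.numeric(coef), all(is.finite(coef)))
  (exp(coef) - 1) * 100
}

#' Two-stage residual inclusion (2SRI) control-function estimator
#'
#' The full two-step procedure: (1) probit of the binary endogenous exposure
#' on controls and excluded instruments; (2) the generalized residuals of that
#' fit enter the outcome model (Poisson by default, NB2 or OLS for sensitivity
#' and placebo analyses) alongside controls and the exposure. The coefficient
#' on the residual term (`gen_resid`) estimates the endogeneity loading; its
#' z-test is the endogeneity test.
#'
#' Inference accounts for the generated regressor by a nonparametric pairs
#' bootstrap: rows are resampled with replacement and *both* stages re-run per
#' replicate; the replicate spread gives the bootstrap covariance and
#' percentile intervals. Replicates where either stage fails are logged and
#' excluded; more than 10 percent failures aborts. The naive single-stage
#' robust covariance is also kept (flagged as understating uncertainty).
#'
#' @param data Prepared analysis table (filtered, imputed).
#' @param roles A [cf_roles()] declaration.
#' @param family `"poisson"` (default), `"negbin"`, or `"ols"`.
#' @param outcome Optional outcome column overriding `roles$outcome`.
#' @param n_boot Bootstrap replicates; 0 skips the bootstrap.
#' @param seed Seed for the bootstrap resampling.
#' @param level Confidence level for reported intervals.
#' @param second_roles Optional roles for the second stage only (the placebo
#'   harness uses this: the placebo variable stays in the selection equation
#'   but cannot regress on itself).
#' @return An object of class `cf_2sri_fit`: `first_stage` (`probit_fit`),
#'   `residuals` (generalized residuals), `second_stage` (`count_fit` with
#'   bootstrap covariance attached), `boot` details, `roles`, `family`.
#' @export
fit_cf_2sri <- function(data, roles, family = c("poisson", "negbin", "ols"),
                        outcome = NULL, n_boot = 500L, seed = 1L,
                        level = 0.95, second_roles = NULL) {
  family <- match.arg(family)
  fitter <- switch(family, poisson = fit_poisson, negbin = fit_negbin,
                   ols = fit_ols)
  roles2 <- second_roles %||% roles
  first <- fit_probit(data, roles)
  gr <- generalized_residual(first$y, first$linear_index)
  second <- fitter(data, roles2, residual = gr, outcome = outcome)

  boot <- NULL
  if (n_boot > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    n <- nrow(data)
    draws <- matrix(NA_real_, n_boot, length(second$coefficients),
                    dimnames = list(NULL, names(second$coefficients)))
    failures <- 0L
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      rep_fit <- tryCatch({
        d <- data[idx, , drop = FALSE]
        f1 <- fit_probit(d, roles)
        g1 <- generalized_residual(f1$y, f1$linear_index)
        fitter(d, roles2, residual = g1, outcome = outcome)$coefficients
      }, error = function(e) NULL)
      if (is.null(rep_fit)) failures <- failures + 1L else draws[b, ] <- rep_fit
    }
    if (failures > 0.10 * n_boot) {
      stop("bootstrap failed in ", failures, " of ", n_boot,
           " replicates; check the specification", call. = FALSE)
    }
    ok <- stats::complete.cases(draws)
    vc <- stats::cov(draws[ok, , drop = FALSE])
    a2 <- (1 - level) / 2
    ci <- t(apply(draws[ok, , drop = FALSE], 2, stats::quantile,
                  probs = c(a2, 1 - a2)))
    colnames(ci) <- c("conf_low", "conf_high")
    boot <- list(n_boot = n_boot, n_failed = failures, vcov = vc,
                 ci_percentile = ci, draws = draws[ok, , drop = FALSE],
                 seed = seed)
    second$vcov_bootstrap <- vc
    second$boot <- boot
  }
  structure(
    list(first_stage = first, residuals = gr, second_stage = second,
         boot = boot, roles = roles, family = family, level = level,
         n = nrow(data)),
    class = "cf_2sri_fit"
  )
}

#' Endogeneity z-test on the generalized-residual coefficient
#'
#' The z-statistic and p-value for the null that the endogeneity loading is
#' zero (exposure exogenous), using the bootstrap standard error when
#' available, otherwise the naive robust one.
#'
#' @param fit A `cf_2sri_fit` or a `count_fit` containing a `gen_resid` term.
#' @param use Which covariance to use, `"auto"` (bootstrap when present),
#'   `"bootstrap"`, or `"naive"`.
#' @return A list with `estimate`, `std_error`, `z`, `p_value`.
#' @export
endogeneity_test <- function(fit, use = c("auto", "bootstrap", "naive")) {
  use <- match.arg(use)
  cf <- if (inherits(fit, "cf_2sri_fit")) fit$second_stage else fit
  stopifnot(inherits(cf, "count_fit"))
  if (!"gen_resid" %in% names(cf$coefficients)) {
    stop("fit has no generalized-residual term", call. = FALSE)
  }
  est <- cf$coefficients[["gen_resid"]]
  vc <- switch(use,
    auto = cf$vcov_bootstrap %||% cf$vcov_naive,
    bootstrap = cf$vcov_bootstrap %||%
      stop("no bootstrap covariance available", call. = FALSE),
    naive = cf$vcov_naive)
  se <- sqrt(vc["gen_resid", "gen_resid"])
  z <- est / se
  list(estimate = est, std_error = se, z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' @export
print.count_fit <- function(x, ...) {
  cat("<count_fit> family =", x$family, " n =", x$n,
      " logLik =", format(x$loglik, digits = 6), "\n")
  if (!is.null(x$nb_alpha)) {
    cat("  overdispersion alpha =", format(x$nb_alpha, digits = 4), "\n")
  }
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
print.cf_2sri_fit <- function(x, ...) {
  cat("<cf_2sri_fit> family =", x$family, " n =", x$n, "\n")
  cat("-- second stage --\n")
  print(x$second_stage)
  et <- endogeneity_test(x)
  cat("endogeneity z =", format(et$z, digits = 4),
      " p =", format(et$p_value, digits = 3), "\n")
  invisible(x)
}
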