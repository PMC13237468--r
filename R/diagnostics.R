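# ---- linear IV machinery -----------------------------------------------------

# Residuals of each column of M after least-squares projection on W.
partial_out <- function(M, W) {
  M <- as.matrix(M)
  qr_w <- qr(W)
  M - W %*% qr.coef(qr_w, M)
}

# Assemble the pieces shared by the IV diagnostics: outcome y, endogenous d,
# exogenous design X1 (with intercept), instrument dummy matrix Z, and their
# partialled versions (Frisch-Waugh: X1 projected out).
iv_pieces <- function(data, roles, outcome = NULL) {
  outcome <- outcome %||% roles$outcome
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column '", outcome, "' not found",
                       call. = FALSE)
  d <- data[[roles$exposure]]
  if (anyNA(d)) stop("exposure contains missing values", call. = FALSE)
  X1 <- build_design(data, roles$controls, roles)
  Zfull <- build_design(data, c(roles$controls, roles$instruments), roles)
  zcols <- setdiff(colnames(Zfull), colnames(X1))
  Z <- Zfull[, zcols, drop = FALSE]
  if (ncol(Z) < 1L) stop("no excluded instruments after dummy expansion",
                         call. = FALSE)
  assert_full_rank(Zfull, "the instrument set")
  n <- length(y)
  k_fs <- ncol(X1) + ncol(Z)
  if (n <= k_fs) stop("fewer rows than first-stage parameters", call. = FALSE)
  list(y = y, d = d, X1 = X1, Z = Z, Zfull = Zfull,
       y_t = drop(partial_out(y, X1)), d_t = drop(partial_out(d, X1)),
       Z_t = partial_out(Z, X1), L = ncol(Z), n = n, k_fs = k_fs)
}

#' Linear two-stage least squares
#'
#' 2SLS of the outcome on controls and the single endogenous exposure, using
#' the dummy-expanded excluded instruments, with heteroskedasticity-robust
#' (HC1) covariance. Also exposes the first-stage reduced form: coefficients
#' of the partialled exposure on the partialled instruments. This is the
#' auxiliary linear model on which the rank and over-identification
#' diagnostics are computed.
#'
#' @param data Analysis table.
#' @param roles A [cf_roles()] declaration.
#' @param outcome Optional outcome column overriding `roles$outcome`.
#' @return An object of class `iv_fit` with `coefficients`, `vcov`
#'   (robust), `residuals`, `first_stage_pi`, `L`, `n`.
#' @export
linear_iv_fit <- function(data, roles, outcome = NULL) {
  p <- iv_pieces(data, roles, outcome)
  R <- cbind(p$X1, exposure = p$d)
  colnames(R)[ncol(R)] <- roles$exposure
  W <- cbind(p$X1, p$Z)
  qr_w <- qr(W)
  Rhat <- W %*% qr.coef(qr_w, R)
  A <- crossprod(Rhat, R)
  assert_full_rank(R, "the 2SLS regressor matrix")
  beta <- solve(A, crossprod(Rhat, p$y))
  e <- drop(p$y - R %*% beta)
  Ainv <- solve(A)
  meat <- crossprod(Rhat * e)
  vc <- Ainv %*% meat %*% t(Ainv) * p$n / (p$n - ncol(R))
  dimnames(vc) <- list(colnames(R), colnames(R))
  pi_hat <- qr.coef(qr(p$Z_t), p$d_t)
  structure(
    list(coefficients = stats::setNames(drop(beta), colnames(R)), vcov = vc,
         residuals = e, first_stage_pi = pi_hat, L = p$L, n = p$n,
         k = ncol(R), roles = roles, pieces = p),
    class = "iv_fit"
  )
}

#' @export
print.iv_fit <- function(x, ...) {
  cat("<iv_fit> n =", x$n, " L =", x$L, "\n")
  co <- x$coefficients
  se <- sqrt(diag(x$vcov))
  print(round(cbind(estimate = co, std_error = se), 4))
  invisible(x)
}

#' Kleibergen-Paap rank LM test (under-identification)
#'
#' Heteroskedasticity-robust test that the reduced-form coefficient vector of
#' the single endogenous exposure on the excluded instruments (after
#' partialling out the exogenous controls) has rank zero. With one endogenous
#' regressor the Kleibergen-Paap rank LM statistic is the robust score
#' statistic \eqn{g'\Omega^{-1}g} with \eqn{g = \sum_i \tilde z_i \tilde d_i}
#' and \eqn{\Omega = \sum_i \tilde z_i \tilde z_i' \tilde d_i^2}; degrees of
#' freedom equal the instrument count L. Under i.i.d. homoskedasticity it
#' coincides asymptotically with the Anderson canonical-correlation LM.
#'
#' @inheritParams linear_iv_fit
#' @return List with `statistic`, `df`, `p_value`.
#' @export
kp_rk_lm <- function(data, roles, outcome = NULL) {
  p <- iv_pieces(data, roles, outcome)
  g <- crossprod(p$Z_t, p$d_t)
  Omega <- crossprod(p$Z_t * p$d_t)
  stat <- drop(t(g) %*% solve(Omega, g))
  list(statistic = stat, df = p$L, p_value = chi2_upper_tail(stat, p$L))
}

#' Kleibergen-Paap rank Wald F statistic (weak instruments)
#'
#' The robust Wald form of the rank statistic scaled as an F: the joint
#' heteroskedasticity-robust Wald test of the excluded instruments in the
#' first-stage regression, divided by the instrument count L, with the
#' small-sample adjustment n/(n - k). Under i.i.d. homoskedasticity it agrees
#' with the classical first-stage F on the excluded instruments; it is
#' compared against Stock-Yogo critical values
#' ([stock_yogo_10pct_bias()]).
#'
#' @inheritParams linear_iv_fit
#' @return The F statistic (scalar).
#' @export
kp_rk_wald_f <- function(data, roles, outcome = NULL) {
  p <- iv_pieces(data, roles, outcome)
  qz <- qr(p$Z_t)
  pi_hat <- qr.coef(qz, p$d_t)
  u <- p$d_t - drop(p$Z_t %*% pi_hat)
  ZtZinv <- solve(crossprod(p$Z_t))
  meat <- crossprod(p$Z_t * u)
  V <- ZtZinv %*% meat %*% ZtZinv * p$n / (p$n - p$k_fs)
  drop(t(pi_hat) %*% solve(V, pi_hat)) / p$L
}

#' Cragg-Donald F statistic
#'
#' The classical (non-robust) first-stage F on the excluded instruments after
#' partialling out the exogenous controls; with a single endogenous regressor
#' the Cragg-Donald minimum-eigenvalue statistic reduces to this F.
#'
#' @inheritParams linear_iv_fit
#' @return The F statistic (scalar).
#' @export
cragg_donald_f <- function(data, roles, outcome = NULL) {
  p <- iv_pieces(data, roles, outcome)
  qz <- qr(p$Z_t)
  fitted <- drop(p$Z_t %*% qr.coef(qz, p$d_t))
  rss <- sum((p$d_t - fitted)^2)
  ess <- sum(fitted^2)
  (ess / p$L) / (rss / (p$n - p$k_fs))
}

#' Hansen J over-identification test
#'
#' Two-step efficient-GMM over-identification statistic with
#' heteroskedasticity-robust weighting: the weight matrix is built from 2SLS
#' residuals, the coefficient re-estimated by GMM under that weight, and
#' \eqn{J = n\,\bar g'\,\hat\Omega^{-1} \bar g} evaluated at the GMM estimate.
#' Degrees of freedom are L - 1 (instruments minus the single endogenous
#' regressor). In the just-identified case the statistic is identically zero
#' and the p-value is reported as `NA`. With `homoskedastic = TRUE` the weight
#' collapses to \eqn{\hat\sigma^2 Z'Z/n} and the statistic equals the Sargan
#' statistic from 2SLS residuals.
#'
#' @inheritParams linear_iv_fit
#' @param homoskedastic Use the homoskedastic (Sargan) weighting.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
hansen_j <- function(data, roles, outcome = NULL, homoskedastic = FALSE) {
  p <- iv_pieces(data, roles, outcome)
  if (p$L < 2L) {
    return(list(statistic = 0, df = 0L, p_value = NA_real_))
  }
  R <- cbind(p$X1, p$d)
  W <- p$Zfull
  # first step: 2SLS residuals
  qr_w <- qr(W)
  Rhat <- W %*% qr.coef(qr_w, R)
  beta_2sls <- solve(crossprod(Rhat, R), crossprod(Rhat, p$y))
  e1 <- drop(p$y - R %*% beta_2sls)
  n <- p$n
  Omega <- if (homoskedastic) {
    crossprod(W) * sum(e1^2) / n / n
  } else {
    crossprod(W * e1) / n
  }
  Oi <- solve(Omega)
  ZR <- crossprod(W, R) / n
  Zy <- crossprod(W, p$y) / n
  beta_gmm <- solve(t(ZR) %*% Oi %*% ZR, t(ZR) %*% Oi %*% Zy)
  e2 <- drop(p$y - R %*% beta_gmm)
  gbar <- crossprod(W, e2) / n
  stat <- drop(n * t(gbar) %*% Oi %*% gbar)
  df <- p$L - 1L
  list(statistic = stat, df = df, p_value = chi2_upper_tail(stat, df))
}

#' Upper-tail chi-square probability
#'
#' Survival function of the chi-square distribution, used for the
#' under-identification and over-identification diagnostics.
#'
#' @param statistic Non-negative test statistic.
#' @param df Positive integer degrees of freedom.
#' @return The upper-tail probability.
#' @examples
#' chi2_upper_tail(21.69, 4) # 0.0002 at 4-decimal rounding
#' @export
chi2_upper_tail <- function(statistic, df) {
  if (any(df <= 0) || any(df != round(df))) {
    stop("df must be a positive integer", call. = FALSE)
  }
  if (any(statistic < 0)) stop("statistic must be non-negative", call. = FALSE)
  stats::pchisq(statistic, df = df, lower.tail = FALSE)
}

# Stock-Yogo (2005) critical values for 10% maximal IV relative bias,
# 1 endogenous regressor, L = 3..10 excluded instruments (2SLS).
STOCK_YOGO_10PCT_BIAS <- c(`3` = 9.08, `4` = 10.27, `5` = 10.83, `6` = 11.12,
                           `7` = 11.29, `8` = 11.39, `9` = 11.46, `10` = 11.49)

#' Stock-Yogo weak-instrument critical value (10 percent relative bias)
#'
#' Tabulated first-stage F threshold such that the 2SLS bias is at most 10
#' percent of the OLS bias, for one endogenous regressor and 3-10 excluded
#' instruments. Values outside the tabulation are an explicit error.
#'
#' @param n_endogenous Number of endogenous regressors (must be 1).
#' @param n_instruments Number of excluded instruments (3-10).
#' @return The tabulated critical value (e.g. 10.27 for 4 instruments).
#' @export
stock_yogo_10pct_bias <- function(n_endogenous = 1L, n_instruments) {
  if (n_endogenous != 1L) {
    stop("critical values are tabulated for one endogenous regressor only",
         call. = FALSE)
  }
  key <- as.character(n_instruments)
  if (!key %in% names(STOCK_YOGO_10PCT_BIAS)) {
    stop("no tabulated Stock-Yogo value for ", n_instruments,
         " instruments (tabulated: 3-10)", call. = FALSE)
  }
  unname(STOCK_YOGO_10PCT_BIAS[key])
}

#' Full instrument-diagnostics report
#'
#' Computes, on the linear auxiliary model, the Kleibergen-Paap rank LM test
#' (under-identification), the Kleibergen-Paap rank Wald F and Cragg-Donald F
#' (weak instruments, with the Stock-Yogo 10 percent relative-bias critical
#' value when tabulated), and the Hansen J over-identification test; plus,
#' when a two-stage fit is supplied, the endogeneity z-test on its
#' generalized-residual coefficient. The headline estimator is a count model;
#' these diagnostics deliberately run on the linear 2SLS form of the same
#' design, the standard auxiliary reporting convention for instrument
#' validity.
#'
#' @inheritParams linear_iv_fit
#' @param cf_fit Optional `cf_2sri_fit` for the endogeneity test.
#' @return An object of class `iv_diagnostics` (a list of the statistics).
#' @export
diagnose_instruments <- function(data, roles, outcome = NULL, cf_fit = NULL) {
  lm_test <- kp_rk_lm(data, roles, outcome)
  wald_f <- kp_rk_wald_f(data, roles, outcome)
  cd_f <- cragg_donald_f(data, roles, outcome)
  j <- hansen_j(data, roles, outcome)
  sy <- tryCatch(stock_yogo_10pct_bias(1L, lm_test$df), error = function(e) NA_real_)
  endo <- if (!is.null(cf_fit)) endogeneity_test(cf_fit) else NULL
  structure(
    list(kp_lm = lm_test, kp_wald_f = wald_f, cragg_donald_f = cd_f,
         hansen_j = j, stock_yogo_10pct_bias = sy, endogeneity = endo,
         L = lm_test$df),
    class = "iv_diagnostics"
  )
}

#' @export
print.iv_diagnostics <- function(x, ...) {
  cat("<iv_diagnostics> L =", x$L, "\n")
  cat(sprintf("  KP rk LM      %8.3f  df %d  p %.4f\n",
              x$kp_lm$statistic, x$kp_lm$df, x$kp_lm$p_value))
  cat(sprintf("  KP rk Wald F  %8.3f  (Stock-Yogo 10%% bias: %s)\n",
              x$kp_wald_f,
              ifelse(is.na(x$stock_yogo_10pct_bias), "not tabulated",
                     format(x$stock_yogo_10pct_bias))))
  cat(sprintf("  Cragg-Donald F %7.3f\n", x$cragg_donald_f))
  if (x$hansen_j$df > 0) {
    cat(sprintf("  Hansen J      %8.3f  df %d  p %.4f\n",
                x$hansen_j$statistic, x$hansen_j$df, x$hansen_j$p_value))
  } else {
    cat("  Hansen J       just-identified (0, df 0)\n")
  }
  if (!is.null(x$endogeneity)) {
    cat(sprintf("  endogeneity z %8.3f  p %.4f\n",
                x$endogeneity$z, x$endogeneity$p_value))
  }
  invisible(x)
}
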