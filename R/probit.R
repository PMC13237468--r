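# ---- core probit maximum likelihood (Newton with step halving) --------------

# Log-likelihood of a probit at linear index z for binary y.
probit_loglik <- function(y, z) {
  sum(y * stats::pnorm(z, log.p = TRUE) +
        (1 - y) * stats::pnorm(-z, log.p = TRUE))
}

# Newton-type probit MLE. `penalty` adds a ridge term -penalty/2 * ||alpha||^2
# to the log-likelihood (used as the fallback under perfect separation).
# Deterministic: least-squares initialisation on the qnorm-transformed
# smoothed response, relative log-likelihood tolerance 1e-10, at most 100
# iterations, step halving when a full step does not improve.
probit_mle <- function(y, X, penalty = 0, tol = 1e-10, maxit = 100L) {
  n <- length(y)
  eta0 <- stats::qnorm((y * n + 0.5) / (n + 1))
  alpha <- qr.solve(X, eta0)
  ll <- probit_loglik(y, drop(X %*% alpha)) - penalty / 2 * sum(alpha^2)
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    z <- drop(X %*% alpha)
    gr <- y * mills_ratio(z) - (1 - y) * mills_ratio(-z)
    score <- drop(crossprod(X, gr)) - penalty * alpha
    w <- gr * (gr + z) # negative second derivative of the per-row loglik
    info <- crossprod(X * sqrt(pmax(w, 0))) + penalty * diag(ncol(X))
    step <- solve(info, score)
    # step halving
    for (h in 0:30) {
      cand <- alpha + step / 2^h
      ll_new <- probit_loglik(y, drop(X %*% cand)) -
        penalty / 2 * sum(cand^2)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
    }
    alpha <- cand
    if (abs(ll_new - ll) < tol * (abs(ll) + tol)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  z <- drop(X %*% alpha)
  gr <- y * mills_ratio(z) - (1 - y) * mills_ratio(-z)
  w <- gr * (gr + z)
  info <- crossprod(X * sqrt(pmax(w, 0))) + penalty * diag(ncol(X))
  vcov_info <- solve(info)
  meat <- crossprod(X * gr)
  vcov_robust <- vcov_info %*% meat %*% vcov_info * n / (n - ncol(X))
  dimnames(vcov_info) <- dimnames(vcov_robust) <-
    list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(drop(alpha), colnames(X)),
       linear_index = z, fitted = stats::pnorm(z),
       loglik = probit_loglik(y, z), converged = converged, n_iter = iter,
       vcov_info = vcov_info, vcov_robust = vcov_robust,
       score = drop(crossprod(X, gr)) - penalty * alpha)
}

# Heuristic perfect-separation check: essentially perfect in-sample
# classification together with an exploding coefficient.
probit_separated <- function(fit, y) {
  p <- fit$fitted
  perfect <- all(p[y == 1] > 1 - 1e-6) && all(p[y == 0] < 1e-6)
  perfect && max(abs(fit$coefficients)) > 10
}

#' Fit the first-stage probit selection equation
#'
#' Maximum-likelihood probit of the binary endogenous exposure on the
#' exogenous controls and the excluded instruments, via Newton iterations with
#' step halving (relative log-likelihood tolerance 1e-10, at most 100
#' iterations, convergence reported as an explicit flag). Reference categories
#' are taken from the roles declaration. The reported `vcov` is the robust
#' (sandwich) covariance; the information-based covariance (used by the
#' delta method in [marginal_effects()]) is kept alongside.
#'
#' @param data Analysis table (filtered and imputed; the exposure must be
#'   binary with no missing values).
#' @param roles A [cf_roles()] declaration.
#' @param penalty Optional ridge penalty; the default 0 is the plain MLE.
#'   Perfect separation with `penalty = 0` is an error advising a positive
#'   penalty.
#' @return An object of class `probit_fit` with elements `coefficients`,
#'   `vcov` (robust), `vcov_info`, `linear_index`, `fitted`, `loglik`,
#'   `converged`, `n_iter`.
#' @export
fit_probit <- function(data, roles, penalty = 0) {
  stopifnot(inherits(roles, "cf_roles"))
  y <- data[[roles$exposure]]
  if (is.null(y)) stop("exposure column '", roles$exposure, "' not found",
                       call. = FALSE)
  if (anyNA(y)) stop("exposure contains missing values; impute first",
                     call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("exposure must be binary 0/1", call. = FALSE)
  vars <- c(roles$controls, roles$instruments)
  X <- build_design(data, vars, roles)
  assert_full_rank(X, "the first-stage probit")
  fit <- probit_mle(y, X, penalty = penalty)
  if (penalty == 0 && probit_separated(fit, y)) {
    stop("perfect separation in the first-stage probit; refit with a ",
         "positive `penalty`", call. = FALSE)
  }
  structure(
    list(coefficients = fit$coefficients, vcov = fit$vcov_robust,
         vcov_info = fit$vcov_info, linear_index = fit$linear_index,
         fitted = fit$fitted, loglik = fit$loglik,
         converged = fit$converged, n_iter = fit$n_iter, score = fit$score,
         roles = roles, vars = vars, xlev = attr(X, "xlev"),
         n = length(y), y = y, data = data[, unique(c(vars, roles$exposure)),
                                           drop = FALSE],
         penalty = penalty),
    class = "probit_fit"
  )
}

#' Linear index of a probit fit on (new) data
#'
#' Returns \eqn{x_i'\hat\alpha} per row; the predicted exposure probability is
#' `pnorm()` of this index. Factor levels unseen at fit time are an error.
#'
#' @param fit A `probit_fit`.
#' @param data Table with the model columns; defaults to the fitting data.
#' @return Numeric vector of linear indices.
#' @export
predict_index <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "probit_fit"))
  if (is.null(data)) return(fit$linear_index)
  X <- build_design(data, fit$vars, fit$roles, xlev = fit$xlev)
  drop(X %*% fit$coefficients)
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("<probit_fit> n =", x$n, " logLik =", format(x$loglik, digits = 6),
      if (!x$converged) " (NOT converged)" else "", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Average marginal effects of the probit first stage
#'
#' For a continuous covariate the effect is the sample average of
#' \eqn{\phi(x_i'\hat\alpha)\hat\alpha_j} (probability points per unit).
#' For a factor level (and for binary 0/1 covariates) it is the discrete
#' change from the base category: the average of
#' \eqn{\Phi(x_i'\hat\alpha \mid \mathrm{level}) -
#' \Phi(x_i'\hat\alpha \mid \mathrm{base})} with every row switched to the
#' level and to the base in turn. Standard errors are by the delta method on
#' the information-based covariance; 95 percent normal confidence bounds.
#'
#' @param fit A converged `probit_fit`.
#' @param data Table to average over; defaults to the fitting data.
#' @return A tibble with columns `term`, `level`, `effect`, `std_error`,
#'   `conf_low`, `conf_high`, `kind`.
#' @export
marginal_effects <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "probit_fit"))
  if (!fit$converged) stop("first-stage probit did not converge", call. = FALSE)
  if (is.null(data)) data <- fit$data
  data <- apply_reference_levels(data, fit$roles, fit$vars)
  X <- build_design(data, fit$vars, fit$roles, xlev = fit$xlev)
  a <- fit$coefficients
  V <- fit$vcov_info
  z <- drop(X %*% a)
  phi <- stats::dnorm(z)

  rows <- list()
  for (v in fit$vars) {
    col <- data[[v]]
    if (is.factor(col) || is.character(col)) {
      col <- if (is.factor(col)) col else factor(col)
      lev <- levels(col)
      base <- lev[1L]
      d_base <- data; d_base[[v]] <- factor(base, levels = lev)
      Xb <- build_design(d_base, fit$vars, fit$roles, xlev = fit$xlev)
      zb <- drop(Xb %*% a)
      for (l in lev[-1L]) {
        d_l <- data; d_l[[v]] <- factor(l, levels = lev)
        Xl <- build_design(d_l, fit$vars, fit$roles, xlev = fit$xlev)
        zl <- drop(Xl %*% a)
        eff <- mean(stats::pnorm(zl) - stats::pnorm(zb))
        grad <- colMeans(stats::dnorm(zl) * Xl - stats::dnorm(zb) * Xb)
        se <- sqrt(drop(t(grad) %*% V %*% grad))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          term = v, level = l, effect = eff, std_error = se,
          kind = "discrete-from-base")
      }
    } else if (all(col %in% c(0, 1))) {
      d1 <- data; d1[[v]] <- 1
      d0 <- data; d0[[v]] <- 0
      X1 <- build_design(d1, fit$vars, fit$roles, xlev = fit$xlev)
      X0 <- build_design(d0, fit$vars, fit$roles, xlev = fit$xlev)
      z1 <- drop(X1 %*% a); z0 <- drop(X0 %*% a)
      eff <- mean(stats::pnorm(z1) - stats::pnorm(z0))
      grad <- colMeans(stats::dnorm(z1) * X1 - stats::dnorm(z0) * X0)
      se <- sqrt(drop(t(grad) %*% V %*% grad))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term = v, level = "1", effect = eff, std_error = se,
        kind = "discrete-from-base")
    } else {
      j <- match(v, colnames(X))
      if (is.na(j)) next
      eff <- mean(phi) * a[j]
      # gradient: d/da_k mean(phi(z) a_j) = a_j * mean(-z phi(z) X_k) + 1{k=j} mean(phi)
      grad <- a[j] * colMeans(-z * phi * X)
      grad[j] <- grad[j] + mean(phi)
      se <- sqrt(drop(t(grad) %*% V %*% grad))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        term = v, level = NA_character_, effect = eff, std_error = se,
        kind = "continuous-AME")
    }
  }
  out <- dplyr::bind_rows(rows)
  out$conf_low <- out$effect - stats::qnorm(0.975) * out$std_error
  out$conf_high <- out$effect + stats::qnorm(0.975) * out$std_error
  out[, c("term", "level", "effect", "std_error", "conf_low", "conf_high",
          "kind")]
}
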