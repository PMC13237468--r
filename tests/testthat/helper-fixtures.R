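# Shared fixtures, built in code. The cache avoids re-simulating the standard
# mid-sized table across test files within one run.

.fixture_cache <- new.env(parent = emptyenv())

# A prepared mid-sized synthetic table under default conditions (no
# missingness so estimation tests are not confounded with imputation).
standard_table <- function(n = 4000, seed = 42, delta = 0.3,
                           missing_rate = 0) {
  key <- paste(n, seed, delta, missing_rate, sep = "_")
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  cfg <- sim_config(n_individuals = n, delta = delta,
                    missing_rate = missing_rate)
  tab <- tibble::as_tibble(strip_truth(simulate_survey(cfg, seed = seed)))
  if (missing_rate > 0) tab <- impute_mhm(tab)$data
  .fixture_cache[[key]] <- tab
  tab
}

standard_cf_fit <- function() {
  if (is.null(.fixture_cache$cf_fit)) {
    .fixture_cache$cf_fit <- fit_cf_2sri(standard_table(), default_roles(),
                                         n_boot = 0)
  }
  .fixture_cache$cf_fit
}

# Minimal roles over a compact design used by hand-built fixtures.
toy_roles <- function() {
  cf_roles(outcome = "y", exposure = "d", instruments = "z",
           controls = "x")
}

# Simulate simple linear IV data: d = Z pi + v, y = beta d + u with
# corr(u, v) = rho_uv; Z is L standard-normal instruments, one exogenous
# control x enters both equations. Optionally heteroskedastic errors or one
# invalid instrument (direct effect on y).
sim_linear_iv <- function(n, L = 4, pi = rep(0.4, L), beta = 1.5,
                          rho_uv = 0.4, seed = 1, heteroskedastic = FALSE,
                          invalid = 0) {
  set.seed(seed)
  Z <- matrix(rnorm(n * L), n, L, dimnames = list(NULL, paste0("z", 1:L)))
  x <- rnorm(n)
  v <- rnorm(n)
  u <- rho_uv * v + sqrt(1 - rho_uv^2) * rnorm(n)
  if (heteroskedastic) u <- u * sqrt(0.3 + 0.7 * x^2)
  d <- drop(Z %*% pi) + 0.5 * x + v
  y <- beta * d + 0.8 * x + invalid * Z[, 1] + u
  out <- tibble::as_tibble(as.data.frame(Z))
  out$x <- x
  out$d <- d
  out$y <- y
  out
}

linear_iv_roles <- function(L = 4) {
  cf_roles(outcome = "y", exposure = "d",
           instruments = paste0("z", 1:L), controls = "x")
}

# Independent Newton-Raphson oracle for the Poisson log-link MLE, written
# directly from the score equations X'(y - exp(X b)) = 0.
poisson_newton_oracle <- function(y, X, tol = 1e-12, maxit = 200) {
  b <- rep(0, ncol(X))
  b[1] <- log(mean(y) + 0.1)
  for (i in seq_len(maxit)) {
    mu <- drop(exp(X %*% b))
    score <- drop(crossprod(X, y - mu))
    info <- crossprod(X * sqrt(mu))
    step <- solve(info, score)
    b <- b + step
    if (max(abs(step)) < tol) break
  }
  b
}
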