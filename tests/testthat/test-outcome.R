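test_that("saturated Poisson recovers log cell means exactly", {
  set.seed(11)
  tab <- tibble::tibble(
    d = rep(c(0L, 1L), each = 50),
    z = rbinom(100, 1, 0.5),
    y = c(rpois(50, 1.7), rpois(50, 2.6))
  )
  roles <- cf_roles(outcome = "y", exposure = "d", instruments = "z",
                    controls = character(0))
  fit <- fit_poisson(tab, roles)
  # with only an intercept and the exposure, the MLE reproduces the two cell
  # means in closed form
  m0 <- mean(tab$y[tab$d == 0]); m1 <- mean(tab$y[tab$d == 1])
  expect_equal(unname(fit$coefficients[["(Intercept)"]]), log(m0),
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients[["d"]]), log(m1 / m0),
               tolerance = 1e-10)
})

test_that("Poisson coefficients match an independent Newton oracle", {
  tab <- tibble::tibble(
    d = c(0L, 1L, 0L, 1L, 1L),
    x = c(0.2, -1.1, 0.5, 1.4, -0.3),
    z = c(1, 0, 0, 1, 1),
    y = c(1L, 3L, 0L, 5L, 2L)
  )
  roles <- cf_roles(outcome = "y", exposure = "d", instruments = "z",
                    controls = "x")
  fit <- fit_poisson(tab, roles)
  X <- cbind(1, tab$x, tab$d)
  oracle <- poisson_newton_oracle(tab$y, X)
  expect_equal(unname(fit$coefficients), unname(oracle), tolerance = 1e-8)
})

test_that("Poisson validates the outcome and reproduces the mean total", {
  tab <- standard_table(n = 1500, seed = 71)
  roles <- default_roles()
  fit <- fit_poisson(tab, roles)
  expect_lt(abs(sum(fit$fitted) - sum(tab$ceb)), 1e-6 * sum(tab$ceb))
  bad <- tab; bad$ceb[1] <- -1L
  expect_error(fit_poisson(bad, roles), "non-negative")
  bad2 <- tab; bad2$ceb <- bad2$ceb + 0.5
  expect_error(fit_poisson(bad2, roles), "integer")
})

test_that("naive Poisson is consistent for the exposure effect when exogenous", {
  cfg <- sim_config(n_individuals = 30000, gamma = 0.05, delta = 0,
                    missing_rate = 0)
  tab <- tibble::as_tibble(strip_truth(simulate_survey(cfg, seed = 81)))
  fit <- fit_poisson(tab, default_roles())
  se <- sqrt(fit$vcov_naive["mhm", "mhm"])
  expect_lt(abs(fit$coefficients[["mhm"]] - 0.05), 3 * se)
})

test_that("NB2 collapses to Poisson on equidispersed data and nests it", {
  cfg <- sim_config(n_individuals = 20000, delta = 0, missing_rate = 0)
  tab <- tibble::as_tibble(strip_truth(simulate_survey(cfg, seed = 91)))
  roles <- default_roles()
  nb <- fit_negbin(tab, roles)
  expect_lt(nb$nb_alpha, 0.01)
  expect_gt(nb$equidispersion$p_value, 0.05)
  pois <- fit_poisson(tab, roles)
  # NB2 log-likelihood evaluated at the Poisson solution with alpha ~ 0
  # agrees with the Poisson log-likelihood (nesting)
  mu <- pois$fitted
  ll_nb_limit <- sum(dnbinom(tab$ceb, mu = mu, size = 1e10, log = TRUE))
  expect_lt(abs(ll_nb_limit - pois$loglik), 1e-4 * abs(pois$loglik))
})

test_that("NB2 recovers a true overdispersion parameter", {
  cfg <- sim_config(n_individuals = 20000, delta = 0, missing_rate = 0)
  tab <- tibble::as_tibble(strip_truth(simulate_survey(cfg, seed = 95)))
  # redraw the outcome as NB2 with alpha = 0.5 around the same conditional mean
  set.seed(95)
  mu <- rep(exp(0.8), nrow(tab))
  alpha_true <- 0.5
  tab$ceb <- rnbinom(nrow(tab), mu = mu, size = 1 / alpha_true)
  nb <- fit_negbin(tab, default_roles())
  expect_lt(abs(nb$nb_alpha - alpha_true), 0.1)
  expect_lt(nb$equidispersion$p_value, 1e-6)
})

test_that("the percentage-change transform is exact and monotone", {
  expect_equal(irr_percent(log(2)), 100)
  expect_equal(irr_percent(0), 0)
  x <- seq(-1, 1, by = 0.1)
  expect_true(all(diff(irr_percent(x)) > 0))
  expect_error(irr_percent(Inf), "finite")
})

test_that("OLS second stage solves the normal equations", {
  tab <- tibble::tibble(
    d = c(0L, 1L, 0L, 1L),
    x = c(0, 1, 2, 3),
    z = c(1, 0, 1, 0),
    y = c(1.0, 2.5, 3.1, 4.9)
  )
  roles <- cf_roles(outcome = "y", exposure = "d", instruments = "z",
                    controls = "x")
  fit <- fit_ols(tab, roles)
  X <- cbind(1, tab$x, tab$d)
  beta <- solve(crossprod(X), crossprod(X, tab$y))
  expect_equal(unname(fit$coefficients), drop(beta), tolerance = 1e-10)
  # exact linear outcome: zero residual sum of squares
  tab2 <- tab
  tab2$y <- 2 + 0.5 * tab2$x - 1 * tab2$d
  fit2 <- fit_ols(tab2, roles)
  expect_lt(sum((tab2$y - fit2$fitted)^2), 1e-20)
})

test_that("an all-zero residual column reduces 2SRI to the naive fit", {
  tab <- standard_table(n = 1000, seed = 66)
  roles <- default_roles()
  naive <- fit_poisson(tab, roles)
  forced <- fit_poisson(tab, roles, residual = rep(0, nrow(tab)))
  expect_equal(forced$coefficients, naive$coefficients, tolerance = 1e-12)
})

test_that("the two-stage fit composes stages and bootstraps deterministically", {
  tab <- standard_table(n = 1200, seed = 121)
  roles <- default_roles()
  fit <- fit_cf_2sri(tab, roles, n_boot = 30, seed = 5)
  # the residual column is exactly the generalized residual of the first stage
  expect_equal(fit$residuals,
               generalized_residual(tab$mhm, fit$first_stage$linear_index))
  expect_true("gen_resid" %in% names(fit$second_stage$coefficients))
  # bootstrap determinism
  fit2 <- fit_cf_2sri(tab, roles, n_boot = 30, seed = 5)
  expect_identical(fit$boot$vcov, fit2$boot$vcov)
  expect_identical(fit$boot$ci_percentile, fit2$boot$ci_percentile)
  # percentile intervals and glance wiring
  expect_true(all(fit$boot$ci_percentile[, 1] <= fit$boot$ci_percentile[, 2]))
  gl <- glance(fit)
  expect_equal(gl$n_boot, 30)
  et <- endogeneity_test(fit)
  expect_equal(et$estimate,
               unname(fit$second_stage$coefficients[["gen_resid"]]))
  et_naive <- endogeneity_test(fit, use = "naive")
  expect_false(identical(et$std_error, et_naive$std_error))
})

test_that("the 2SRI fitted means approach the oracle as endogeneity shrinks", {
  gaps <- sapply(c(0.8, 0.6, 0.3, 0.1, 0), function(delta) {
    cfg <- sim_config(n_individuals = 15000, delta = delta, missing_rate = 0)
    tab <- tibble::as_tibble(simulate_survey(cfg, seed = 200))
    vis <- tibble::as_tibble(strip_truth(tab))
    fit <- fit_cf_2sri(vis, default_roles(), n_boot = 0)
    X <- get("second_stage_design", envir = asNamespace("cfcount"))(
      transform(vis, gen_resid = fit$residuals), default_roles(), "gen_resid")
    pred <- drop(exp(X %*% fit$second_stage$coefficients))
    oracle <- oracle_conditional_mean(tab$.sel_index, tab$mhm,
                                      tab$.out_index, cfg$gamma, delta)
    mean(abs(pred - oracle))
  })
  # the gap falls with |delta| until it reaches the sampling-noise floor,
  # so non-increase is asserted up to a small Monte Carlo allowance
  expect_true(all(diff(gaps) <= 0.01))
  expect_gt(gaps[1], gaps[5] + 0.05)
})

test_that("tidy and the report table expose percentage-change effects", {
  fit <- standard_cf_fit()
  td <- tidy(fit)
  expect_true("irr_percent" %in% names(td))
  expect_equal(td$irr_percent, irr_percent(td$estimate))
  gl <- glance(fit$second_stage)
  expect_identical(gl$family, "poisson")
})
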