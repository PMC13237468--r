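# White-box access to the Newton core for designs the roles interface cannot
# express (e.g. a pure intercept).
probit_core <- function(d, X) {
  get("probit_mle", envir = asNamespace("cfcount"))(d, X)
}

predict_index_with <- function(fit, data, coefs) {
  fit$coefficients <- coefs
  predict_index(fit, data)
}

test_that("intercept-only probit recovers qnorm of the response mean", {
  d <- rep(c(0L, 1L), 50)
  X <- matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- probit_core(d, X)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients[1]), 0, tolerance = 1e-8)

  d2 <- c(rep(0L, 3), rep(1L, 7))
  fit2 <- probit_core(d2, matrix(1, 10, 1, dimnames = list(NULL, "(Intercept)")))
  expect_equal(unname(fit2$coefficients[1]), qnorm(0.7), tolerance = 1e-8)
})

test_that("probit MLE beats a dense grid on a six-row fixture", {
  tab <- tibble::tibble(
    d = c(0L, 1L, 0L, 1L, 1L, 0L),
    z = c(0, 0, 1, 1, 1, 0),
    y = c(0L, 1L, 2L, 1L, 3L, 2L)
  )
  roles <- cf_roles(outcome = "y", exposure = "d", instruments = "z",
                    controls = character(0))
  fit <- fit_probit(tab, roles)
  expect_true(fit$converged)
  X <- cbind(1, tab$z)
  ll <- function(a) sum(tab$d * pnorm(drop(X %*% a), log.p = TRUE) +
                          (1 - tab$d) * pnorm(-drop(X %*% a), log.p = TRUE))
  grid <- seq(-5, 5, length.out = 101)
  best_grid <- max(outer(grid, grid,
                         Vectorize(function(a1, a2) ll(c(a1, a2)))))
  expect_gte(fit$loglik + 1e-10, best_grid)
})

test_that("probit recovers the generating coefficients on synthetic data", {
  cfg <- sim_config(n_individuals = 20000, missing_rate = 0)
  tab <- tibble::as_tibble(strip_truth(simulate_survey(cfg, seed = 61)))
  fit <- fit_probit(tab, default_roles())
  se <- sqrt(diag(fit$vcov))
  sc <- default_sel_coefs()
  expected <- c(
    washdwelling_wash = sc$wash[["dwelling_wash"]],
    washdwelling_only = sc$wash[["dwelling_only"]],
    washelsewhere_wash = sc$wash[["elsewhere_wash"]],
    washelsewhere_only = sc$wash[["elsewhere_only"]],
    wealthmiddle = sc$wealth[["middle"]],
    wealthpoor = sc$wealth[["poor"]],
    educationprimary = sc$education[["primary"]],
    educationnone = sc$education[["none"]],
    age = sc$age,
    residencerural = sc$residence[["rural"]],
    media_any = sc$media_any,
    head_sexfemale = sc$head_sex[["female"]],
    head_age = sc$head_age,
    `(Intercept)` = sc$intercept - sc$age * 32 - sc$head_age * 50
  )
  for (nm in names(expected)) {
    expect_lt(abs(fit$coefficients[[nm]] - expected[[nm]]), 3 * se[[nm]],
              label = paste("recovery of", nm))
  }
})

test_that("marginal effects match closed forms for a single binary covariate", {
  set.seed(4)
  tab <- tibble::tibble(d = rbinom(200, 1, 0.5), w = rbinom(200, 1, 0.5),
                        y = rpois(200, 1))
  roles <- cf_roles(outcome = "y", exposure = "d", instruments = "w",
                    controls = character(0))
  fit <- fit_probit(tab, roles)
  # impose alpha = (0, 1): the discrete effect must be Phi(1) - Phi(0)
  fit$coefficients[] <- c(0, 1)
  me <- marginal_effects(fit)
  expect_equal(me$effect[me$term == "w"], pnorm(1) - pnorm(0),
               tolerance = 1e-12)
  expect_identical(me$kind[me$term == "w"], "discrete-from-base")
  expect_true(all(me$conf_low <= me$effect & me$effect <= me$conf_high))
  expect_true(all(abs(me$effect[me$kind == "discrete-from-base"]) <= 1))
  # zero coefficients give zero effects
  fit$coefficients[] <- c(0, 0)
  me0 <- marginal_effects(fit)
  expect_true(all(me0$effect == 0))
})

test_that("WASH marginal effects are positive and ordered like the truth", {
  tab <- standard_table()
  fit <- fit_probit(tab, default_roles())
  me <- marginal_effects(fit)
  w <- me[me$term == "wash", ]
  expect_true(all(w$effect > 0))
  alpha <- default_sel_coefs()$wash
  expect_identical(order(w$effect), order(alpha[sub("^wash", "", w$level)]))
})

test_that("predict_index reproduces the linear index and rejects unseen levels", {
  tab <- standard_table(n = 500, seed = 14)
  fit <- fit_probit(tab, default_roles())
  expect_equal(predict_index(fit, tab), fit$linear_index, tolerance = 1e-12)
  bad <- tab[1:5, ]
  bad$wealth <- factor("destitute")
  expect_error(predict_index(fit, bad), "level|factor")
})

test_that("shifting a covariate by a constant only moves the intercept", {
  tab <- standard_table(n = 2000, seed = 26)
  roles <- default_roles()
  fit1 <- fit_probit(tab, roles)
  tab2 <- tab
  tab2$age <- tab2$age + 10
  fit2 <- fit_probit(tab2, roles)
  keep <- setdiff(names(fit1$coefficients), "(Intercept)")
  expect_equal(fit1$coefficients[keep], fit2$coefficients[keep],
               tolerance = 1e-6)
  gr1 <- generalized_residual(tab$mhm, fit1$linear_index)
  gr2 <- generalized_residual(tab2$mhm, fit2$linear_index)
  expect_equal(gr1, gr2, tolerance = 1e-6)
  me1 <- marginal_effects(fit1)
  me2 <- marginal_effects(fit2)
  expect_equal(me1$effect, me2$effect, tolerance = 1e-6)
})

test_that("the fitted log-likelihood dominates random perturbations (concavity)", {
  tab <- standard_table(n = 1000, seed = 33)
  fit <- fit_probit(tab, default_roles())
  ll_at <- function(a) {
    z <- predict_index_with(fit, tab, a)
    sum(tab$mhm * pnorm(z, log.p = TRUE) +
          (1 - tab$mhm) * pnorm(-z, log.p = TRUE))
  }
  set.seed(99)
  for (i in 1:5) {
    dir <- rnorm(length(fit$coefficients))
    perturbed <- fit$coefficients + 0.1 * dir / sqrt(sum(dir^2))
    expect_gte(fit$loglik + 1e-8, ll_at(perturbed))
  }
})

test_that("rank deficiency and separation raise informative errors", {
  tab <- standard_table(n = 300, seed = 44)
  tab$age_copy <- tab$age
  roles_bad <- cf_roles(outcome = "ceb", exposure = "mhm",
                        instruments = "wash",
                        controls = c("age", "age_copy"),
                        reference_levels = list(wash = "none"))
  expect_error(fit_probit(tab, roles_bad), "collinear")

  set.seed(7)
  sep <- tibble::tibble(
    d = c(rep(0L, 30), rep(1L, 30)),
    x = c(rnorm(30, 0), rnorm(30, 8)), # complete separation on x
    z = rnorm(60), y = rpois(60, 1)
  )
  roles_sep <- cf_roles(outcome = "y", exposure = "d", instruments = "z",
                        controls = "x")
  expect_error(fit_probit(sep, roles_sep), "separation")
  pen <- fit_probit(sep, roles_sep, penalty = 1)
  expect_true(all(is.finite(pen$coefficients)))
})

test_that("a probit fit exposes sane metadata and tidiers", {
  tab <- standard_table(n = 800, seed = 50)
  fit <- fit_probit(tab, default_roles())
  expect_true(fit$converged)
  expect_lt(max(abs(fit$score)), 1e-4)
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "conf_low") %in%
                    names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, 800)
})
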