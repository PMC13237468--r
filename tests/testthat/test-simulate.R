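test_that("simulation is deterministic given config and seed", {
  cfg <- sim_config(n_individuals = 300)
  a <- simulate_survey(cfg, seed = 9)
  b <- simulate_survey(cfg, seed = 9)
  expect_identical(a, b)
  c_ <- simulate_survey(cfg, seed = 10)
  expect_false(identical(a$mhm, c_$mhm))
})

test_that("per-stage random streams are independent", {
  cfg1 <- sim_config(n_individuals = 500, missing_rate = 0.05)
  cfg2 <- sim_config(n_individuals = 500, missing_rate = 0.30)
  a <- simulate_survey(cfg1, seed = 4)
  b <- simulate_survey(cfg2, seed = 4)
  # changing the missingness stage leaves covariates, selection, outcome alone
  expect_identical(a$ceb, b$ceb)
  expect_identical(a$.epsilon, b$.epsilon)
  expect_identical(a$wealth, b$wealth)
  # changing outcome coefficients leaves the exposure alone
  oc <- default_out_coefs(); oc$intercept <- 0.2
  cfg3 <- sim_config(n_individuals = 500, out_coefs = oc)
  d <- simulate_survey(cfg3, seed = 4)
  expect_identical(a$mhm, d$mhm)
  expect_false(identical(a$ceb, d$ceb))
})

test_that("configuration validation names the offending variable", {
  expect_error(sim_config(category_probabilities =
                            list(wealth = c(rich = 0.5, middle = 0.2,
                                            poor = 0.4))),
               "wealth")
  expect_error(sim_config(category_probabilities =
                            list(education = c(`secondary+` = -0.1,
                                               primary = 0.6, none = 0.5))),
               "education")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(n_individuals = 0), "n_individuals")
  expect_error(sim_config(sel_coefs = list(intercept = 0, nonsense = 1)),
               "nonsense")
})

test_that("a single-row draw is complete", {
  tab <- simulate_survey(sim_config(n_individuals = 1, missing_rate = 0),
                         seed = 5)
  expect_equal(nrow(tab), 1L)
  expect_false(anyNA(strip_truth(tab)))
})

test_that("sampled category shares match the configured marginals", {
  cfg <- sim_config(
    n_individuals = 10000,
    category_probabilities = list(wealth = c(rich = 0.40, middle = 0.20,
                                             poor = 0.40)))
  tab <- generate_covariates(cfg, seed = 21)
  shares <- as.numeric(table(tab$wealth) / nrow(tab))
  target <- c(0.40, 0.20, 0.40)
  se <- sqrt(target * (1 - target) / nrow(tab))
  expect_true(all(abs(shares - target) <= 3 * se))
})

test_that("selection follows the probit law", {
  # alpha = 0: P(exposure) = Phi(0) = 0.5
  cfg0 <- sim_config(n_individuals = 20000, sel_coefs = list(intercept = 0),
                     missing_rate = 0)
  tab0 <- generate_selection(generate_covariates(cfg0, 8), cfg0, 8)
  expect_lt(abs(mean(tab0$mhm) - 0.5), 3 * sqrt(0.25 / 20000))
  # deep-tail intercept: essentially no exposure
  cfg_neg <- sim_config(n_individuals = 5000,
                        sel_coefs = list(intercept = -10), missing_rate = 0)
  tab_neg <- generate_selection(generate_covariates(cfg_neg, 8), cfg_neg, 8)
  expect_equal(mean(tab_neg$mhm), 0, tolerance = 1e-6)
  # general alpha: empirical mean matches mean of Phi(X alpha) exactly computed
  cfg <- sim_config(n_individuals = 20000, missing_rate = 0)
  tab <- generate_selection(generate_covariates(cfg, 13), cfg, 13)
  p_true <- pnorm(tab$.sel_index)
  se <- sqrt(sum(p_true * (1 - p_true))) / nrow(tab)
  expect_lt(abs(mean(tab$mhm) - mean(p_true)), 3 * se)
  # hard invariant: exposure = 1 exactly when index + epsilon >= 0
  expect_identical(tab$mhm, as.integer(tab$.sel_index + tab$.epsilon >= 0))
})

test_that("exposure probability ordering follows the WASH coefficients", {
  cfg <- sim_config(n_individuals = 20000, missing_rate = 0)
  tab <- generate_selection(generate_covariates(cfg, 17), cfg, 17)
  p_by_wash <- tapply(tab$mhm, tab$wash, mean)
  alpha <- c(none = 0, default_sel_coefs()$wash)
  expect_identical(order(p_by_wash[names(alpha)]), order(alpha))
})

test_that("the outcome stage draws from the configured Poisson law", {
  # pure Poisson(2): delta = gamma = 0, intercept log 2
  cfg <- sim_config(n_individuals = 20000,
                    sel_coefs = list(intercept = 0),
                    out_coefs = list(intercept = log(2)),
                    gamma = 0, delta = 0, missing_rate = 0)
  tab <- simulate_survey(cfg, seed = 31)
  expect_lt(abs(mean(tab$ceb) - 2), 3 * sqrt(2 / 20000))
  expect_true(all(tab$ceb >= 0 & tab$ceb == round(tab$ceb)))
  # overflow guard
  cfg_bad <- sim_config(n_individuals = 10,
                        out_coefs = list(intercept = 25), missing_rate = 0)
  expect_error(simulate_survey(cfg_bad, seed = 1), "overflow|log-mean")
  # ordering of stages enforced
  cov_only <- generate_covariates(cfg, 1)
  expect_error(generate_outcome(cov_only, cfg, 1), "selection")
})

test_that("simulated cell means match the closed-form oracle", {
  # single-cell design: no covariate variation, so every row shares X
  cfg <- sim_config(n_individuals = 40000,
                    sel_coefs = list(intercept = 0.2),
                    out_coefs = list(intercept = 0.5),
                    gamma = 0.05, delta = 0.5, missing_rate = 0)
  tab <- simulate_survey(cfg, seed = 23)
  for (d in 0:1) {
    cell <- tab$ceb[tab$mhm == d]
    expect_gt(length(cell), 1000)
    oracle <- oracle_conditional_mean(0.2, d, 0.5, 0.05, 0.5)
    expect_lt(abs(mean(cell) - oracle), 4 * sd(cell) / sqrt(length(cell)))
  }
})

test_that("the conditional-mean oracle has its closed-form properties", {
  # no endogeneity: reduces to the plain log-link mean
  expect_equal(oracle_conditional_mean(0.7, 1, 0.3, 0.1, 0),
               exp(0.3 + 0.1), tolerance = 1e-12)
  expect_equal(oracle_conditional_mean(0.7, 0, 0.3, 0.1, 0), exp(0.3),
               tolerance = 1e-12)
  # direct evaluation at the reference point
  expect_equal(oracle_conditional_mean(0, 1, 0, 0, 0.3),
               exp(0.045) * pnorm(0.3) / 0.5, tolerance = 1e-12)
  # cross-check by numerical integration of exp(delta * e) phi(e) over e >= -Xa
  num <- integrate(function(e) exp(0.3 * e) * dnorm(e), lower = 0,
                   upper = Inf)$value / pnorm(0)
  expect_equal(oracle_conditional_mean(0, 1, 0, 0, 0.3), num,
               tolerance = 1e-8)
  # reflection symmetry of the normal
  for (z in c(-1.2, 0, 0.8)) {
    expect_equal(oracle_conditional_mean(z, 1, 0, 0, 0.4),
                 oracle_conditional_mean(-z, 0, 0, 0, -0.4),
                 tolerance = 1e-12)
  }
})

test_that("missingness is MCAR with the configured rate and deterministic", {
  cfg <- sim_config(n_individuals = 10000, missing_rate = 0.05)
  tab <- simulate_survey(cfg, seed = 77)
  n_miss <- sum(is.na(tab$mhm))
  expect_lt(abs(n_miss - 500), 3 * sqrt(10000 * 0.05 * 0.95))
  expect_identical(which(is.na(tab$mhm)), which(tab$mhm_missing == 1))
  tab2 <- simulate_survey(cfg, seed = 77)
  expect_identical(which(is.na(tab2$mhm)), which(is.na(tab$mhm)))
  # rate 0 leaves the exposure untouched
  cfg0 <- sim_config(n_individuals = 1000, missing_rate = 0)
  expect_false(anyNA(simulate_survey(cfg0, seed = 3)$mhm))
})

test_that("truth columns are hidden from exports", {
  tab <- simulate_survey(sim_config(n_individuals = 50), seed = 2)
  expect_true(any(startsWith(names(tab), ".")))
  vis <- strip_truth(tab)
  expect_false(any(startsWith(names(vis), ".")))
  path <- file.path(tempdir(), "sim_export.csv")
  paths <- write_survey(tab, path)
  on.exit(unlink(paths))
  main <- utils::read.csv(path)
  expect_false(any(grepl("epsilon|true_mean|sel_index", names(main))))
  truth <- utils::read.csv(sub("\\.csv$", ".truth.csv", path))
  expect_true(all(c("X.epsilon", "X.true_mean") %in% names(truth)) ||
                all(c(".epsilon", ".true_mean") %in% names(truth)))
})

test_that("questionnaire items reproduce the exposure under the all-yes rule", {
  tab <- simulate_survey(sim_config(n_individuals = 2000, missing_rate = 0),
                         seed = 12)
  rebuilt <- construct_mhm(tab$q_privacy, tab$q_materials, tab$q_reuse)
  expect_identical(rebuilt, tab$mhm)
})

test_that("the copula hook induces dependence without changing marginals", {
  cfg_dep <- sim_config(n_individuals = 20000, copula_rho = 0.6)
  tab <- generate_covariates(cfg_dep, seed = 6)
  shares <- as.numeric(table(tab$wealth) / nrow(tab))
  expect_true(all(abs(shares - c(0.4, 0.2, 0.4)) <
                    3 * sqrt(0.4 * 0.6 / 20000) + 0.02))
  # wealth and education become positively associated under the shared factor
  tab_ind <- generate_covariates(sim_config(n_individuals = 20000), seed = 6)
  assoc <- function(t) suppressWarnings(
    chisq.test(table(t$wealth, t$education))$statistic)
  expect_gt(assoc(tab), assoc(tab_ind))
})
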