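#' Configuration for the synthetic survey generator
#'
#' Builds the configuration object consumed by [simulate_survey()] and the
#' stage functions [generate_covariates()], [generate_selection()],
#' [generate_outcome()] and [apply_missingness()]. Defaults emulate a national
#' household survey of ever-married women aged 15-49 in a West African setting:
#' category shares follow published descriptive tables (five-category WASH
#' availability near 2/24/9.5/42/23 percent, wealth 40/20/40, education
#' 29/35/36, media exposure 78 percent, 5 percent missingness on the
#' menstrual-hygiene indicator), and the structural parameters encode a latent
#' normal error shared between the probit selection equation for the exposure
#' and the log-linear Poisson fertility process, so the exposure is endogenous
#' by construction with known strength.
#'
#' Coefficient lists are keyed by covariate: scalar entries for numeric or
#' binary covariates (age and head age enter centred at 32 and 50 years), named
#' vectors over non-reference levels for factors. The selection index is
#' \eqn{x_i'\alpha}, the exposure is \eqn{1[x_i'\alpha + \varepsilon_i \ge 0]}
#' with \eqn{\varepsilon_i \sim N(0,1)}, and the outcome is Poisson with
#' log-mean \eqn{x_{1i}'\beta + \gamma d_i + \delta \varepsilon_i}; `delta`
#' is the endogeneity loading \eqn{E(e_i|\varepsilon_i) = \delta\varepsilon_i}
#' and `gamma` the exposure effect on the log-mean.
#'
#' @param n_individuals Number of respondents; default 4989.
#' @param category_probabilities Named list of probability vectors for
#'   `wash`, `wealth`, `education`, `region`, `ethnicity` and binary rates
#'   `rural`, `media`, `contraception`, `nicotine_alcohol`, `female_head`.
#'   Each vector must be non-negative and sum to 1 within 1e-12.
#' @param age_range,head_age_range Integer bounds for respondent and
#'   household-head ages.
#' @param sel_coefs Selection-equation coefficients (alpha), a named list.
#' @param out_coefs Outcome-equation coefficients (beta), a named list.
#' @param gamma Exposure effect on the log-mean.
#' @param delta Endogeneity loading.
#' @param missing_rate Fraction of the exposure set missing completely at
#'   random, in [0, 1).
#' @param copula_rho Optional equicorrelation of the Gaussian copula across the
#'   latent uniforms driving the covariate draws; 0 (default) gives independent
#'   covariates.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 4989,
                       category_probabilities = list(),
                       age_range = c(15L, 49L),
                       head_age_range = c(25L, 75L),
                       sel_coefs = default_sel_coefs(),
                       out_coefs = default_out_coefs(),
                       gamma = 0.05,
                       delta = 0.3,
                       missing_rate = 0.05,
                       copula_rho = 0) {
  probs <- utils::modifyList(default_category_probabilities(),
                             category_probabilities)
  for (nm in c("wash", "wealth", "education", "region", "ethnicity")) {
    p <- probs[[nm]]
    if (any(p < 0)) {
      stop("probability vector for '", nm, "' has negative entries",
           call. = FALSE)
    }
    if (abs(sum(p) - 1) > 1e-12) {
      stop("probability vector for '", nm, "' does not sum to 1 (got ",
           format(sum(p), digits = 15), ")", call. = FALSE)
    }
  }
  for (nm in c("rural", "media", "contraception", "nicotine_alcohol",
               "female_head")) {
    p <- probs[[nm]]
    if (length(p) != 1L || p < 0 || p > 1) {
      stop("rate for '", nm, "' must be a single probability", call. = FALSE)
    }
  }
  if (!(length(n_individuals) == 1L && n_individuals >= 1)) {
    stop("n_individuals must be >= 1", call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  }
  if (copula_rho < 0 || copula_rho >= 1) {
    stop("copula_rho must lie in [0, 1)", call. = FALSE)
  }
  validate_coef_list(sel_coefs, probs, "sel_coefs")
  validate_coef_list(out_coefs, probs, "out_coefs")
  structure(
    list(n_individuals = as.integer(n_individuals),
         category_probabilities = probs,
         age_range = as.integer(age_range),
         head_age_range = as.integer(head_age_range),
         sel_coefs = sel_coefs, out_coefs = out_coefs,
         gamma = gamma, delta = delta,
         missing_rate = missing_rate, copula_rho = copula_rho),
    class = "sim_config"
  )
}

# Default category shares. The printed WASH shares (2, 23.7, 9.5, 42, 23)
# add to 100.2 percent; they are renormalised proportionally. Education
# (29/35/35 printed, sums to 99) takes the remainder on the top category.
default_category_probabilities <- function() {
  wash <- c(none = 0.020, dwelling_wash = 0.237, dwelling_only = 0.095,
            elsewhere_wash = 0.420, elsewhere_only = 0.230)
  list(
    wash = wash / sum(wash),
    wealth = c(rich = 0.40, middle = 0.20, poor = 0.40),
    education = c(`secondary+` = 0.36, primary = 0.35, none = 0.29),
    region = stats::setNames(rep(1 / 5, 5), paste0("region_", 1:5)),
    ethnicity = stats::setNames(rep(1 / 5, 5), paste0("ethnicity_", 1:5)),
    rural = 0.60, media = 0.78, contraception = 0.62,
    nicotine_alcohol = 0.75, female_head = 0.25
  )
}

#' @rdname sim_config
#' @export
default_sel_coefs <- function() {
  list(
    intercept = -0.35,
    wash = c(dwelling_wash = 1.75, dwelling_only = 1.15,
             elsewhere_wash = 1.35, elsewhere_only = 0.95),
    wealth = c(middle = -0.45, poor = -0.50),
    education = c(primary = -0.15, none = -0.35),
    age = 0.012,
    residence = c(rural = -0.15),
    media_any = -0.18,
    head_sex = c(female = 0.30),
    head_age = -0.005,
    head_education = c(primary = -0.12, none = -0.20)
  )
}

#' @rdname sim_config
#' @export
default_out_coefs <- function() {
  list(
    intercept = 1.16,
    age = 0.02,
    education = c(primary = -0.10, none = -0.30),
    wealth = c(middle = -0.09, poor = -0.30),
    residence = c(rural = 0.05),
    media_any = -0.03,
    contraception_any = -0.13,
    nicotine_or_alcohol = -0.03,
    head_sex = c(female = 0.25),
    head_age = 0.001,
    head_education = c(primary = -0.05, none = -0.10)
  )
}

# Covariates a coefficient list may reference, with the factor levels that are
# legal for each.
coef_vocabulary <- function(probs) {
  list(
    intercept = NULL,
    age = NULL, head_age = NULL,
    media_any = NULL, contraception_any = NULL, nicotine_or_alcohol = NULL,
    wash = names(probs$wash)[-1L],
    wealth = names(probs$wealth)[-1L],
    education = names(probs$education)[-1L],
    head_education = names(probs$education)[-1L],
    region = names(probs$region)[-1L],
    ethnicity = names(probs$ethnicity)[-1L],
    residence = "rural",
    head_sex = "female"
  )
}

validate_coef_list <- function(coefs, probs, what) {
  vocab <- coef_vocabulary(probs)
  unknown <- setdiff(names(coefs), names(vocab))
  if (length(unknown)) {
    stop("unknown covariate name(s) in ", what, ": ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(coefs)) {
    lv <- vocab[[nm]]
    if (is.null(lv)) next
    bad <- setdiff(names(coefs[[nm]]), lv)
    if (length(bad)) {
      stop("unknown level(s) for '", nm, "' in ", what, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

# Ages enter the structural indices centred so the intercept is interpretable
# at a typical respondent.
AGE_CENTER <- 32
HEAD_AGE_CENTER <- 50

# Evaluate a coefficient list against a covariate table.
linear_index_from_coefs <- function(data, coefs) {
  idx <- rep(coefs$intercept %||% 0, nrow(data))
  for (nm in setdiff(names(coefs), "intercept")) {
    val <- coefs[[nm]]
    if (length(val) > 1L || !is.null(names(val))) {
      contrib <- val[as.character(data[[nm]])]
      contrib[is.na(contrib)] <- 0 # reference level
      idx <- idx + unname(contrib)
    } else {
      x <- data[[nm]]
      if (nm == "age") x <- x - AGE_CENTER
      if (nm == "head_age") x <- x - HEAD_AGE_CENTER
      idx <- idx + val * x
    }
  }
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent per-stage seeds derived from one master seed, so that toggling
# one generation stage leaves the draws of the others untouched.
stage_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(2147483646L, 4L),
                  c("covariates", "selection", "outcome", "missingness"))
}

# Inverse-CDF draw of a categorical from a uniform.
draw_categorical <- function(u, probs) {
  lev <- names(probs)
  cuts <- cumsum(probs)
  factor(lev[findInterval(u, c(0, cuts[-length(cuts)]))], levels = lev)
}

#' Draw the covariate table
#'
#' Samples `n_individuals` rows of socio-demographic covariates per the
#' configured marginal distributions. Draws are made by inverse CDF from a
#' matrix of uniforms; with `copula_rho > 0` the uniforms share a Gaussian
#' copula with equicorrelation `copula_rho`, otherwise covariates are
#' independent. The WASH category is also expanded into the four consistent
#' facility indicator columns (`water_dwelling`, `water_elsewhere`,
#' `handwash_place`, `hand_cleanser`) so the variable-construction stage can be
#' exercised on simulated data. All rows satisfy the eligibility criteria of
#' the analysis sample (ever married, aged 15-49, no hysterectomy, not
#' menopausal).
#'
#' @param config A [sim_config()] object.
#' @param seed Integer seed; draws are deterministic given `config` and `seed`.
#' @return A tibble with one row per respondent.
#' @export
generate_covariates <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- stage_seeds(seed)
  n <- config$n_individuals
  probs <- config$category_probabilities

  vars <- c("age", "head_age", "education", "wealth", "wash", "region",
            "ethnicity", "rural", "media", "contraception",
            "nicotine_alcohol", "female_head")
  withr_seed <- seeds[["covariates"]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(withr_seed)

  k <- length(vars)
  if (config$copula_rho > 0) {
    common <- stats::rnorm(n)
    z <- sqrt(config$copula_rho) * matrix(common, n, k) +
      sqrt(1 - config$copula_rho) * matrix(stats::rnorm(n * k), n, k)
    u <- stats::pnorm(z)
  } else {
    u <- matrix(stats::runif(n * k), n, k)
  }
  colnames(u) <- vars

  age_lo <- config$age_range[1]; age_hi <- config$age_range[2]
  hage_lo <- config$head_age_range[1]; hage_hi <- config$head_age_range[2]

  wash <- draw_categorical(u[, "wash"], probs$wash)
  water_dwelling <- as.integer(wash %in% c("dwelling_wash", "dwelling_only"))
  water_elsewhere <- as.integer(wash %in% c("elsewhere_wash", "elsewhere_only"))
  has_wash <- wash %in% c("dwelling_wash", "elsewhere_wash")
  # split the "with washing facilities" categories between a handwash place,
  # a cleanser, or both, reusing the same uniform for determinism
  u_split <- (u[, "wash"] * 997) %% 1
  handwash_place <- as.integer(has_wash & u_split < 0.8)
  hand_cleanser <- as.integer(has_wash & u_split > 0.3)

  tibble::tibble(
    id = seq_len(n),
    age = pmin(floor(age_lo + u[, "age"] * (age_hi - age_lo + 1)), age_hi),
    marital_status = "married",
    hysterectomy = 0L,
    menopause = 0L,
    education = draw_categorical(u[, "education"], probs$education),
    residence = factor(ifelse(u[, "rural"] < probs$rural, "rural", "urban"),
                       levels = c("urban", "rural")),
    region = draw_categorical(u[, "region"], probs$region),
    ethnicity = draw_categorical(u[, "ethnicity"], probs$ethnicity),
    wealth = draw_categorical(u[, "wealth"], probs$wealth),
    head_sex = factor(ifelse(u[, "female_head"] < probs$female_head,
                             "female", "male"),
                      levels = c("male", "female")),
    head_age = pmin(floor(hage_lo + u[, "head_age"] * (hage_hi - hage_lo + 1)),
                    hage_hi),
    head_education = draw_categorical((u[, "education"] * 991) %% 1,
                                      probs$education),
    media_any = as.integer(u[, "media"] < probs$media),
    contraception_any = as.integer(u[, "contraception"] < probs$contraception),
    nicotine_or_alcohol = as.integer(u[, "nicotine_alcohol"] <
                                       probs$nicotine_alcohol),
    wash = wash,
    water_dwelling = water_dwelling,
    water_elsewhere = water_elsewhere,
    handwash_place = handwash_place,
    hand_cleanser = hand_cleanser
  )
}

#' Draw the endogenous exposure
#'
#' Adds the latent standard-normal selection error and the binary exposure
#' `mhm` \eqn{= 1[x_i'\alpha + \varepsilon_i \ge 0]}. Also emits the three
#' questionnaire items (`q_privacy`, `q_materials`, `q_reuse`) consistent with
#' the exposure under the all-yes rule: respondents with `mhm = 1` answer yes
#' to all three, respondents with `mhm = 0` answer no to at least one. Hidden
#' truth columns `.epsilon` and `.sel_index` are prefixed with a dot and are
#' stripped by [strip_truth()] before any estimation-facing export.
#'
#' @param data Covariate table from [generate_covariates()].
#' @param config A [sim_config()] object.
#' @param seed Integer master seed (the selection stage uses its own stream).
#' @return `data` with columns `mhm`, questionnaire items, and hidden truth
#'   columns.
#' @export
generate_selection <- function(data, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  validate_coef_list(config$sel_coefs, config$category_probabilities,
                     "sel_coefs")
  needed <- setdiff(names(config$sel_coefs), "intercept")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("sel_coefs references covariates absent from the table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  seeds <- stage_seeds(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seeds[["selection"]])

  n <- nrow(data)
  sel_index <- linear_index_from_coefs(data, config$sel_coefs)
  epsilon <- stats::rnorm(n)
  mhm <- as.integer(sel_index + epsilon >= 0)

  # questionnaire items consistent with the all-yes construction rule
  u1 <- stats::runif(n); u2 <- stats::runif(n); u3 <- stats::runif(n)
  q_privacy <- ifelse(mhm == 1, "yes", ifelse(u1 < 0.6, "yes", "no"))
  q_materials <- ifelse(mhm == 1, "yes", ifelse(u2 < 0.7, "yes", "no"))
  q_reuse <- ifelse(mhm == 1, "yes", ifelse(u3 < 0.5, "yes", "no"))
  all_yes <- mhm == 0 & q_privacy == "yes" & q_materials == "yes" &
    q_reuse == "yes"
  q_materials[all_yes] <- "no"

  data$mhm <- mhm
  data$q_privacy <- q_privacy
  data$q_materials <- q_materials
  data$q_reuse <- q_reuse
  data$.sel_index <- sel_index
  data$.epsilon <- epsilon
  data
}

#' Draw the count outcome
#'
#' Adds the fertility outcome: `ceb` (children ever born) is Poisson with
#' log-mean \eqn{x_{1i}'\beta + \gamma\,d_i + \delta\,\varepsilon_i}, sharing
#' the selection error \eqn{\varepsilon_i} so the exposure is endogenous when
#' \eqn{\delta \ne 0}. `live_births` is a binomially thinned copy (retention
#' 0.95) used as the sensitivity outcome. The hidden column `.true_mean`
#' records the conditional Poisson mean used for each draw. Configurations
#' whose maximum log-mean exceeds 20 are rejected (overflow guard).
#'
#' @param data Table from [generate_selection()].
#' @param config A [sim_config()] object.
#' @param seed Integer master seed (the outcome stage uses its own stream).
#' @return `data` with `ceb`, `live_births` and hidden `.true_mean`.
#' @export
generate_outcome <- function(data, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!all(c("mhm", ".epsilon") %in% names(data))) {
    stop("selection must be generated before the outcome", call. = FALSE)
  }
  seeds <- stage_seeds(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seeds[["outcome"]])

  out_index <- linear_index_from_coefs(data, config$out_coefs)
  log_mean <- out_index + config$gamma * data$mhm + config$delta * data$.epsilon
  if (max(log_mean) > 20) {
    stop("maximum outcome log-mean ", format(max(log_mean), digits = 4),
         " exceeds the overflow bound of 20; rescale out_coefs", call. = FALSE)
  }
  mu <- exp(log_mean)
  data$ceb <- stats::rpois(nrow(data), mu)
  data$live_births <- stats::rbinom(nrow(data), data$ceb, 0.95)
  data$.out_index <- out_index
  data$.true_mean <- mu
  data
}

#' Closed-form conditional mean of the outcome given the observed exposure
#'
#' Under the generating model -- probit selection with latent error
#' \eqn{\varepsilon}, Poisson outcome with log-mean
#' \eqn{x_1'\beta + \gamma d + \delta\varepsilon} -- the mean of the outcome
#' conditional on covariates and the *observed* exposure has the closed form
#' \deqn{E[y \mid x, d = 1] = e^{x_1'\beta + \gamma + \delta^2/2}\,
#'   \Phi(x'\alpha + \delta)/\Phi(x'\alpha),}
#' \deqn{E[y \mid x, d = 0] = e^{x_1'\beta + \delta^2/2}\,
#'   \Phi(-x'\alpha - \delta)/\Phi(-x'\alpha),}
#' from the moment generating function of a one-sided truncated standard
#' normal. This oracle validates both the simulator (cell means must agree
#' with it) and the approximation error of two-stage residual inclusion.
#'
#' @param x_index Selection linear index \eqn{x'\alpha}.
#' @param exposed Observed exposure, 0 or 1 (vectorized).
#' @param beta_part Outcome-equation linear index \eqn{x_1'\beta}.
#' @param gamma Exposure effect on the log-mean.
#' @param delta Endogeneity loading.
#' @return The exact conditional mean.
#' @examples
#' oracle_conditional_mean(0, 1, 0, 0, 0.3) # exp(0.045) * pnorm(0.3) / 0.5
#' @export
oracle_conditional_mean <- function(x_index, exposed, beta_part, gamma, delta) {
  stopifnot(all(exposed %in% c(0, 1)))
  log_ratio_1 <- stats::pnorm(x_index + delta, log.p = TRUE) -
    stats::pnorm(x_index, log.p = TRUE)
  log_ratio_0 <- stats::pnorm(-x_index - delta, log.p = TRUE) -
    stats::pnorm(-x_index, log.p = TRUE)
  ifelse(exposed == 1,
         exp(beta_part + gamma + delta^2 / 2 + log_ratio_1),
         exp(beta_part + delta^2 / 2 + log_ratio_0))
}

#' Set the exposure missing completely at random
#'
#' Masks the configured fraction of the exposure column (MCAR) and records a
#' `mhm_missing` flag. With `missing_rate = 0` the table is returned unchanged
#' apart from the (all-zero) flag. The missing set is deterministic given the
#' master seed.
#'
#' @param data Table containing an `mhm` column.
#' @param config A [sim_config()] object.
#' @param seed Integer master seed (the missingness stage uses its own stream).
#' @return `data` with `mhm` partially set to `NA` and a `mhm_missing` flag.
#' @export
apply_missingness <- function(data, config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (!"mhm" %in% names(data)) stop("no mhm column present", call. = FALSE)
  seeds <- stage_seeds(seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seeds[["missingness"]])
  miss <- stats::runif(nrow(data)) < config$missing_rate
  data$mhm_missing <- as.integer(miss)
  data$mhm[miss] <- NA_integer_
  data
}

#' Generate a complete synthetic survey
#'
#' Runs the four generation stages (covariates, selection, outcome,
#' missingness) under one master seed with independent per-stage streams.
#'
#' @param config A [sim_config()] object; defaults to `sim_config()`.
#' @param seed Integer master seed.
#' @return A tibble with analysis columns plus hidden truth columns (names
#'   starting with a dot); see [strip_truth()].
#' @examples
#' tab <- simulate_survey(sim_config(n_individuals = 200), seed = 7)
#' mean(tab$ceb)
#' @export
simulate_survey <- function(config = sim_config(), seed = 1L) {
  data <- generate_covariates(config, seed)
  data <- generate_selection(data, config, seed)
  data <- generate_outcome(data, config, seed)
  apply_missingness(data, config, seed)
}

#' Drop hidden truth columns
#'
#' Removes every column whose name begins with a dot (latent error, true
#' indices, true conditional mean) so that estimation stages never see the
#' generating truth.
#'
#' @param data A simulated table.
#' @return The table without truth columns.
#' @export
strip_truth <- function(data) {
  data[, !startsWith(names(data), "."), drop = FALSE]
}

#' Write a simulated survey to CSV with a truth sidecar
#'
#' The analysis-facing table (truth columns removed) is written to `path`; the
#' hidden truth columns, keyed by `id`, go to a sidecar file with suffix
#' `.truth.csv`.
#'
#' @param data A simulated table.
#' @param path Output CSV path.
#' @return Invisibly, the two paths written.
#' @export
write_survey <- function(data, path) {
  visible <- strip_truth(data)
  utils::write.csv(visible, path, row.names = FALSE, na = "")
  truth_cols <- names(data)[startsWith(names(data), ".")]
  truth_path <- sub("\\.csv$", ".truth.csv", path)
  if (identical(truth_path, path)) truth_path <- paste0(path, ".truth.csv")
  truth <- cbind(data["id"], data[truth_cols])
  utils::write.csv(truth, truth_path, row.names = FALSE, na = "")
  invisible(c(path, truth_path))
}
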