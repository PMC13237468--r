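#' Construct the binary menstrual-hygiene indicator from three questionnaire items
#'
#' The indicator is 1 when the respondent answered yes to all three items
#' (ability to wash and change in privacy, use of menstrual materials, and the
#' reusability item), 0 when at least one answer is no, and missing when any
#' item is missing. Answers are matched case-insensitively against
#' `"yes"`/`"no"`; any other non-missing code is a parse error reporting the
#' offending row index.
#'
#' @param q_privacy,q_materials,q_reuse Vectors of `"yes"`/`"no"`/`NA`.
#' @return Integer vector in \{0, 1, NA\}.
#' @examples
#' construct_mhm("yes", "yes", "yes") # 1
#' construct_mhm("yes", "no", "yes") # 0
#' @export
construct_mhm <- function(q_privacy, q_materials, q_reuse) {
  norm <- function(x, what) {
    x <- tolower(trimws(as.character(x)))
    x[x == ""] <- NA_character_
    bad <- which(!is.na(x) & !x %in% c("yes", "no"))
    if (length(bad)) {
      stop("unrecognized answer code in ", what, " at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "),
           ": '", x[bad[1]], "'", call. = FALSE)
    }
    x
  }
  a <- norm(q_privacy, "q_privacy")
  b <- norm(q_materials, "q_materials")
  c_ <- norm(q_reuse, "q_reuse")
  out <- as.integer(a == "yes" & b == "yes" & c_ == "yes")
  out[is.na(a) | is.na(b) | is.na(c_)] <- NA_integer_
  out
}

#' Apply the inclusion and exclusion filters
#'
#' Retains ever-married women aged 15-49 with no hysterectomy who are not
#' menopausal. Rules are applied in the fixed order marital status,
#' hysterectomy, menopause, age, so the per-rule drop counts in the audit are
#' reproducible. Applying the filters twice equals applying them once.
#'
#' @param data Table with columns `marital_status`, `hysterectomy`,
#'   `menopause`, `age`.
#' @param age_range Inclusive age bounds, default `c(15, 49)`.
#' @return A list with `data` (the retained rows, as a tibble) and `audit`
#'   (a tibble of rule names and rows dropped per rule, in application order).
#' @export
apply_filters <- function(data, age_range = c(15, 49)) {
  required <- c("marital_status", "hysterectomy", "menopause", "age")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing filter columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  steps <- list(
    marital = function(d) d$marital_status != "never_married",
    hysterectomy = function(d) !(d$hysterectomy %in% 1 | d$hysterectomy %in% TRUE),
    menopause = function(d) !(d$menopause %in% 1 | d$menopause %in% TRUE),
    age = function(d) d$age >= age_range[1] & d$age <= age_range[2]
  )
  dropped <- integer(length(steps))
  names(dropped) <- names(steps)
  for (i in seq_along(steps)) {
    keep <- steps[[i]](data)
    keep[is.na(keep)] <- FALSE
    dropped[i] <- sum(!keep)
    data <- data[keep, , drop = FALSE]
  }
  list(data = data,
       audit = tibble::tibble(rule = names(dropped), dropped = unname(dropped)))
}

#' Collapse the five wealth quintiles into three classes
#'
#' Rich and richest map to `"rich"` (code 0), middle to `"middle"` (code 1),
#' poor and poorest to `"poor"` (code 2). Unknown quintile labels are an
#' error, never silently dropped.
#'
#' @param quintile Vector of quintile labels among
#'   `poorest, poor, middle, rich, richest` (case-insensitive).
#' @return Factor with levels `rich`, `middle`, `poor` (in code order 0, 1, 2).
#' @export
recode_wealth <- function(quintile) {
  q <- tolower(trimws(as.character(quintile)))
  map <- c(poorest = "poor", poor = "poor", middle = "middle",
           rich = "rich", richest = "rich")
  bad <- which(!is.na(q) & !q %in% names(map))
  if (length(bad)) {
    stop("unknown wealth quintile '", q[bad[1]], "' at row ", bad[1],
         call. = FALSE)
  }
  factor(unname(map[q]), levels = c("rich", "middle", "poor"))
}

#' Construct the five-category WASH availability variable
#'
#' Classifies each household by where water (for uses other than drinking) is
#' available and whether washing facilities accompany it:
#' \describe{
#'   \item{none}{no water access (the reference category; covers the
#'     respondents lacking water, handwashing facilities and cleansers)}
#'   \item{dwelling_wash}{water within the dwelling/yard/plot with a
#'     handwashing place and/or hand cleanser}
#'   \item{dwelling_only}{water within the dwelling/yard/plot without washing
#'     facilities}
#'   \item{elsewhere_wash}{water elsewhere with a handwashing place and/or
#'     cleanser}
#'   \item{elsewhere_only}{water elsewhere without washing facilities}
#' }
#' Rows claiming water both at the dwelling and elsewhere are contradictory
#' and raise a validation error.
#'
#' @param water_dwelling,water_elsewhere,handwash_place,hand_cleanser Binary
#'   (0/1) vectors.
#' @return Factor with the five levels above, reference `none`.
#' @export
construct_wash_category <- function(water_dwelling, water_elsewhere,
                                    handwash_place, hand_cleanser) {
  for (v in list(water_dwelling, water_elsewhere, handwash_place,
                 hand_cleanser)) {
    if (!all(v %in% c(0, 1), na.rm = TRUE)) {
      stop("WASH inputs must be binary 0/1", call. = FALSE)
    }
  }
  contradiction <- which(water_dwelling == 1 & water_elsewhere == 1)
  if (length(contradiction)) {
    stop("contradictory water availability (both dwelling and elsewhere) at ",
         "row(s) ", paste(utils::head(contradiction, 5), collapse = ", "),
         call. = FALSE)
  }
  wash <- handwash_place == 1 | hand_cleanser == 1
  out <- ifelse(water_dwelling == 1, ifelse(wash, "dwelling_wash", "dwelling_only"),
         ifelse(water_elsewhere == 1, ifelse(wash, "elsewhere_wash", "elsewhere_only"),
                "none"))
  factor(out, levels = c("none", "dwelling_wash", "dwelling_only",
                         "elsewhere_wash", "elsewhere_only"))
}

#' Impute missing exposure values by probit regression
#'
#' Fits a probit of the observed exposure on water availability at the
#' dwelling and the three-class wealth variable, then replaces missing
#' exposure values either deterministically (`predicted probability >= 0.5`,
#' the default, producing a single imputed dataset) or stochastically (a
#' Bernoulli draw at the predicted probability). Perfect separation in the
#' imputation model falls back to a ridge-penalized probit with a warning.
#'
#' @param data Table with columns `mhm`, `water_dwelling`, `wealth`.
#' @param policy `"deterministic"` (default) or `"stochastic"`.
#' @param seed Seed for the stochastic policy.
#' @return A list with `data` (exposure completed) and `report` (list with
#'   `n_imputed`, `coefficients`, `policy`).
#' @export
impute_mhm <- function(data, policy = c("deterministic", "stochastic"),
                       seed = 1L) {
  policy <- match.arg(policy)
  required <- c("mhm", "water_dwelling", "wealth")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing imputation columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data)
  miss <- is.na(data$mhm)
  if (!any(miss)) {
    return(list(data = data,
                report = list(n_imputed = 0L, coefficients = NULL,
                              policy = policy)))
  }
  if (all(miss)) stop("all exposure values are missing", call. = FALSE)

  obs <- data[!miss, , drop = FALSE]
  imp_roles <- cf_roles(outcome = "mhm", exposure = ".unused_",
                        instruments = "water_dwelling", controls = "wealth",
                        reference_levels = list(wealth = "rich"))
  X <- build_design(obs, c("water_dwelling", "wealth"), imp_roles)
  fit <- tryCatch(
    probit_mle(obs$mhm, X),
    error = function(e) {
      warning("imputation probit failed (", conditionMessage(e),
              "); using ridge-penalized fit", call. = FALSE)
      probit_mle(obs$mhm, X, penalty = 1e-4)
    }
  )
  if (probit_separated(fit, obs$mhm)) {
    warning("perfect separation in the imputation probit; ",
            "using ridge-penalized fit", call. = FALSE)
    fit <- probit_mle(obs$mhm, X, penalty = 1e-4)
  }
  Xmiss <- build_design(data[miss, , drop = FALSE],
                        c("water_dwelling", "wealth"), imp_roles,
                        xlev = attr(X, "xlev"))
  p <- stats::pnorm(drop(Xmiss %*% fit$coefficients))
  imputed <- if (policy == "deterministic") {
    as.integer(p >= 0.5)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    stats::rbinom(length(p), 1L, p)
  }
  data$mhm[miss] <- imputed
  list(data = data,
       report = list(n_imputed = sum(miss), coefficients = fit$coefficients,
                     policy = policy))
}

#' Prepare a raw survey table for estimation
#'
#' Runs the full preparation sequence: derive the exposure from the three
#' questionnaire items when a raw `mhm` column is absent, derive the WASH
#' category from the facility indicators when absent, apply the
#' inclusion/exclusion filters, listwise-delete rows missing any analysis
#' variable other than the exposure, and impute missing exposure values.
#'
#' @param data Raw survey table.
#' @param roles A [cf_roles()] declaration (default [default_roles()]).
#' @param impute_policy Passed to [impute_mhm()].
#' @param seed Seed for stochastic imputation.
#' @return A list with `data` (analysis-ready tibble), `audit` (filter drops
#'   plus the listwise-deletion count) and `imputation` (the imputation
#'   report).
#' @export
prepare_survey <- function(data, roles = default_roles(),
                           impute_policy = "deterministic", seed = 1L) {
  data <- tibble::as_tibble(data)
  if (!"mhm" %in% names(data) &&
      all(c("q_privacy", "q_materials", "q_reuse") %in% names(data))) {
    data$mhm <- construct_mhm(data$q_privacy, data$q_materials, data$q_reuse)
  }
  if (!"wash" %in% names(data) &&
      all(c("water_dwelling", "water_elsewhere", "handwash_place",
            "hand_cleanser") %in% names(data))) {
    data$wash <- construct_wash_category(data$water_dwelling,
                                         data$water_elsewhere,
                                         data$handwash_place,
                                         data$hand_cleanser)
  }
  filtered <- apply_filters(data)
  data <- filtered$data

  analysis_vars <- unique(c(roles$outcome, roles$instruments, roles$controls))
  analysis_vars <- intersect(analysis_vars, names(data))
  complete <- stats::complete.cases(data[, analysis_vars, drop = FALSE])
  n_listwise <- sum(!complete)
  data <- data[complete, , drop = FALSE]

  imp <- impute_mhm(data, policy = impute_policy, seed = seed)
  audit <- dplyr::bind_rows(
    filtered$audit,
    tibble::tibble(rule = "listwise_nonmissing", dropped = n_listwise)
  )
  list(data = imp$data, audit = audit, imputation = imp$report)
}
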