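#' Placebo (falsification) test of the exclusion restriction
#'
#' Re-runs the design with a placebo outcome that shares the household's
#' unobserved confounders but has no plausible causal link to the exposure
#' (by default the household head's age): a control-function OLS (the probit
#' first stage is byte-identical to the main pipeline's, only the outcome
#' changes) and a linear IV-2SLS with full instrument diagnostics. An
#' insignificant exposure coefficient supports the exclusion restriction; an
#' insignificant generalized-residual term rules out endogeneity with respect
#' to the placebo outcome.
#'
#' @param data Prepared analysis table.
#' @param roles A [cf_roles()] declaration (its outcome is replaced).
#' @param placebo_outcome Column name of the continuous placebo outcome.
#' @param level Significance level for the verdict flags.
#' @param n_boot Bootstrap replicates for the CF-OLS stage (0 = naive robust
#'   inference only).
#' @param seed Bootstrap seed.
#' @return An object of class `placebo_result`: `cf_ols` (a `cf_2sri_fit`
#'   with OLS second stage), `iv_2sls` (`iv_fit`), `diagnostics`
#'   (`iv_diagnostics`), and verdict flags `exclusion_supported`
#'   and `endogeneity_ruled_out`.
#' @export
run_placebo <- function(data, roles, placebo_outcome = "head_age",
                        level = 0.05, n_boot = 0L, seed = 1L) {
  stopifnot(inherits(roles, "cf_roles"))
  if (identical(placebo_outcome, roles$outcome)) {
    stop("placebo outcome equals the true outcome; refused", call. = FALSE)
  }
  y <- data[[placebo_outcome]]
  if (is.null(y)) stop("placebo outcome column '", placebo_outcome,
                       "' not found", call. = FALSE)
  if (!is.numeric(y)) stop("placebo outcome must be numeric", call. = FALSE)
  if (stats::var(y) == 0) {
    stop("placebo outcome is constant; refused", call. = FALSE)
  }
  # the selection equation is untouched (identical first stage); the placebo
  # variable is only removed from the second-stage regressors, where it would
  # regress on itself
  controls2 <- setdiff(roles$controls, placebo_outcome)
  roles_p <- cf_roles(outcome = placebo_outcome, exposure = roles$exposure,
                      instruments = roles$instruments, controls = controls2,
                      reference_levels = roles$reference_levels)
  cf <- fit_cf_2sri(data, roles, family = "ols", outcome = placebo_outcome,
                    n_boot = n_boot, seed = seed, second_roles = roles_p)
  iv <- linear_iv_fit(data, roles_p)
  diag <- diagnose_instruments(data, roles_p, cf_fit = cf)

  zc <- stats::qnorm(1 - level / 2)
  b_iv <- iv$coefficients[[roles$exposure]]
  se_iv <- sqrt(iv$vcov[roles$exposure, roles$exposure])
  exclusion_supported <- abs(b_iv / se_iv) < zc
  endo <- endogeneity_test(cf)
  endogeneity_ruled_out <- endo$p_value > level

  structure(
    list(cf_ols = cf, iv_2sls = iv, diagnostics = diag,
         placebo_outcome = placebo_outcome, level = level,
         exposure_estimate_iv = b_iv, exposure_se_iv = se_iv,
         exclusion_supported = exclusion_supported,
         endogeneity_ruled_out = endogeneity_ruled_out),
    class = "placebo_result"
  )
}

#' @export
print.placebo_result <- function(x, ...) {
  cat("<placebo_result> outcome =", x$placebo_outcome, "\n")
  cat(sprintf("  IV-2SLS exposure coef %.3f (se %.3f) -> exclusion %s\n",
              x$exposure_estimate_iv, x$exposure_se_iv,
              ifelse(x$exclusion_supported, "supported", "NOT supported")))
  et <- endogeneity_test(x$cf_ols)
  cat(sprintf("  CF-OLS residual term %.3f (p = %.3f) -> endogeneity %s\n",
              et$estimate, et$p_value,
              ifelse(x$endogeneity_ruled_out, "ruled out", "NOT ruled out")))
  invisible(x)
}

#' Re-run the two-stage pipeline on a subsample
#'
#' Filters the analysis table (the parent table is never mutated), verifies
#' the subsample is large enough and contains both exposure classes, and
#' re-runs the two-stage control-function estimator and the instrument
#' diagnostics. Used for the heterogeneity analyses (rural residents; younger
#' women aged 15-29).
#'
#' @param data Prepared analysis table.
#' @param roles A [cf_roles()] declaration.
#' @param filter A logical vector of `nrow(data)`, or an unquoted filtering
#'   expression evaluated in the data (e.g. `age <= 29`).
#' @param label Optional name for the subsample in reports.
#' @param min_rows Minimum subsample size (default 500).
#' @param family,n_boot,seed Passed to [fit_cf_2sri()].
#' @return A list with `label`, `n`, `fit` (`cf_2sri_fit`) and `diagnostics`.
#' @export
run_subsample <- function(data, roles, filter, label = NULL, min_rows = 500L,
                          family = "poisson", n_boot = 0L, seed = 1L) {
  expr <- rlang::enquo(filter)
  keep <- rlang::eval_tidy(expr, data = data)
  if (!is.logical(keep) || length(keep) != nrow(data)) {
    stop("filter must evaluate to a logical vector over the rows",
         call. = FALSE)
  }
  keep[is.na(keep)] <- FALSE
  sub <- data[keep, , drop = FALSE]
  if (nrow(sub) == 0L) stop("subsample filter matched zero rows", call. = FALSE)
  if (nrow(sub) < min_rows) {
    stop("subsample has ", nrow(sub), " rows, below the minimum of ",
         min_rows, call. = FALSE)
  }
  classes <- unique(sub[[roles$exposure]])
  if (length(stats::na.omit(classes)) < 2L) {
    stop("subsample contains a single exposure class", call. = FALSE)
  }
  # controls that the filter makes constant (e.g. residence in the rural
  # subsample) are dropped from the model rather than breaking the design
  constant <- vapply(roles$controls, function(v) {
    length(unique(sub[[v]])) < 2L
  }, logical(1))
  if (any(constant)) {
    keep <- roles$controls[!constant]
    refs <- roles$reference_levels[
      setdiff(names(roles$reference_levels), roles$controls[constant])]
    roles <- cf_roles(outcome = roles$outcome, exposure = roles$exposure,
                      instruments = roles$instruments, controls = keep,
                      reference_levels = refs)
  }
  const_inst <- vapply(roles$instruments, function(v) {
    length(unique(sub[[v]])) < 2L
  }, logical(1))
  if (any(const_inst)) {
    stop("instrument(s) constant in the subsample: ",
         paste(roles$instruments[const_inst], collapse = ", "), call. = FALSE)
  }
  fit <- fit_cf_2sri(sub, roles, family = family, n_boot = n_boot, seed = seed)
  diag <- diagnose_instruments(sub, roles, cf_fit = fit)
  list(label = label %||% rlang::as_label(expr), n = nrow(sub), fit = fit,
       diagnostics = diag)
}
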