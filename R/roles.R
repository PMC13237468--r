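#' Declare model roles for the two-stage analysis
#'
#' A roles object states which columns of the analysis table play which part in
#' the model: the count outcome, the single binary endogenous exposure, the
#' excluded instruments (factor columns whose dummy expansion instruments the
#' exposure), and the exogenous controls. Reference (base) categories for
#' factor columns are fixed here so that every downstream fit, marginal-effect
#' table and report uses the same parameterisation.
#'
#' @param outcome Column name of the count outcome (e.g. children ever born).
#' @param exposure Column name of the binary endogenous exposure.
#' @param instruments Character vector of excluded-instrument columns. Factor
#'   columns are dummy-expanded at fit time; the number of expanded columns is
#'   the instrument count L used for diagnostic degrees of freedom.
#' @param controls Character vector of exogenous control columns.
#' @param reference_levels Named list mapping factor column names to their base
#'   level, e.g. `list(wash = "none", wealth = "rich")`.
#' @return An object of class `cf_roles`.
#' @examples
#' roles <- cf_roles(
#'   outcome = "ceb", exposure = "mhm", instruments = "wash",
#'   controls = c("age", "wealth"), reference_levels = list(wealth = "rich")
#' )
#' @export
cf_roles <- function(outcome, exposure, instruments, controls,
                     reference_levels = list()) {
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.character(exposure), length(exposure) == 1L,
            is.character(instruments), length(instruments) >= 1L,
            is.character(controls))
  if (exposure %in% c(instruments, controls)) {
    stop("the endogenous exposure must not appear among instruments or controls",
         call. = FALSE)
  }
  if (outcome %in% c(instruments, controls, exposure)) {
    stop("the outcome must be distinct from exposure, instruments and controls",
         call. = FALSE)
  }
  if (length(intersect(instruments, controls)) > 0L) {
    stop("columns cannot be both instruments and controls: ",
         paste(intersect(instruments, controls), collapse = ", "), call. = FALSE)
  }
  if (!is.list(reference_levels) ||
      (length(reference_levels) && is.null(names(reference_levels)))) {
    stop("reference_levels must be a named list", call. = FALSE)
  }
  structure(
    list(outcome = outcome, exposure = exposure, instruments = instruments,
         controls = controls, reference_levels = reference_levels),
    class = "cf_roles"
  )
}

#' Default roles for the bundled survey layout
#'
#' Convenience constructor matching the column names produced by
#' [simulate_survey()] and [prepare_survey()]: outcome `ceb`, exposure `mhm`,
#' the five-category WASH availability variable as the excluded instrument and
#' the socio-demographic controls, with reference categories fixed at
#' WASH "none", wealth "rich", education "secondary+", head education
#' "secondary+", urban residence and male household head.
#'
#' @param outcome Outcome column; defaults to `"ceb"`, use `"live_births"` for
#'   the sensitivity outcome.
#' @return A `cf_roles` object.
#' @export
default_roles <- function(outcome = "ceb") {
  cf_roles(
    outcome = outcome,
    exposure = "mhm",
    instruments = "wash",
    controls = c("age", "education", "residence", "region", "ethnicity",
                 "wealth", "head_sex", "head_age", "head_education",
                 "media_any", "contraception_any", "nicotine_or_alcohol"),
    reference_levels = list(
      wash = "none", wealth = "rich", education = "secondary+",
      head_education = "secondary+", residence = "urban", head_sex = "male"
    )
  )
}

#' @export
print.cf_roles <- function(x, ...) {
  cat("<cf_roles>\n")
  cat("  outcome:    ", x$outcome, "\n")
  cat("  exposure:   ", x$exposure, "\n")
  cat("  instruments:", paste(x$instruments, collapse = ", "), "\n")
  cat("  controls:   ", paste(x$controls, collapse = ", "), "\n")
  if (length(x$reference_levels)) {
    refs <- paste(names(x$reference_levels), unlist(x$reference_levels),
                  sep = " = ")
    cat("  references: ", paste(refs, collapse = ", "), "\n")
  }
  invisible(x)
}

# ---- internal design-matrix helpers -----------------------------------------

# Relevel declared factors so the stated base category is first; coerce
# character columns used as factors. Errors on a reference level absent from
# the data.
apply_reference_levels <- function(data, roles, vars = NULL) {
  refs <- roles$reference_levels
  if (is.null(vars)) vars <- names(refs)
  for (v in intersect(vars, names(refs))) {
    if (!v %in% names(data)) next
    col <- data[[v]]
    if (!is.factor(col)) col <- factor(col)
    if (!refs[[v]] %in% levels(col)) {
      stop("reference level '", refs[[v]], "' not present in column '", v, "'",
           call. = FALSE)
    }
    data[[v]] <- stats::relevel(col, ref = refs[[v]])
  }
  data
}

# Build a design matrix (with intercept) for `vars`, honouring reference
# levels and stored factor levels. `xlev` (from a previous fit) makes unseen
# levels an error, which is the contract for prediction.
build_design <- function(data, vars, roles, xlev = NULL) {
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("columns not found in data: ", paste(missing_vars, collapse = ", "),
         call. = FALSE)
  }
  data <- apply_reference_levels(data, roles, vars)
  if (length(vars) == 0L) {
    X <- matrix(1, nrow = nrow(data), dimnames = list(NULL, "(Intercept)"))
    attr(X, "assign") <- 0L
    return(X)
  }
  f <- stats::reformulate(vars)
  mf <- stats::model.frame(f, data = data, na.action = stats::na.fail,
                           xlev = xlev)
  X <- stats::model.matrix(f, mf)
  attr(X, "xlev") <- stats::.getXlevels(stats::terms(mf), mf)
  X
}

# Names of the dummy-expanded instrument columns in a selection design.
instrument_columns <- function(data, roles) {
  data <- apply_reference_levels(data, roles, roles$instruments)
  cols <- character(0)
  for (v in roles$instruments) {
    col <- data[[v]]
    if (is.factor(col) || is.character(col)) {
      col <- if (is.factor(col)) col else factor(col)
      cols <- c(cols, paste0(v, levels(col)[-1L]))
    } else {
      cols <- c(cols, v)
    }
  }
  cols
}

# Rank check with an informative error naming aliased columns.
assert_full_rank <- function(X, context) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient design in ", context, "; collinear columns: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
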