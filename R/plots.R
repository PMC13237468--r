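#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Forest plot of first-stage average marginal effects
#'
#' Marginal effects on the exposure probability with 95 percent intervals,
#' one row per covariate level, discrete effects from the base category.
#'
#' @param object A `probit_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.probit_fit <- function(object, ...) {
  me <- marginal_effects(object)
  me$label <- ifelse(is.na(me$level), me$term, paste(me$term, me$level))
  ggplot2::ggplot(me, ggplot2::aes(x = .data$effect,
                                   y = stats::reorder(.data$label,
                                                      .data$effect))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high,
                                          colour = .data$kind)) +
    ggplot2::labs(x = "average marginal effect on P(exposure = 1)",
                  y = NULL, colour = NULL,
                  title = "First-stage probit: average marginal effects") +
    ggplot2::theme_minimal()
}

#' Forest plot of second-stage percentage-change effects
#'
#' Percentage change in the conditional outcome mean per coefficient
#' (the incidence-rate-ratio transform), with bootstrap intervals when the
#' fit carries them.
#'
#' @param object A `cf_2sri_fit` with a log-link second stage.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cf_2sri_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", , drop = FALSE]
  if (!"irr_percent" %in% names(td)) {
    stop("percentage-change plot requires a log-link second stage",
         call. = FALSE)
  }
  td$pct_low <- irr_percent(td$conf_low)
  td$pct_high <- irr_percent(td$conf_high)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$irr_percent,
                                   y = stats::reorder(.data$term,
                                                      .data$irr_percent))) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$pct_low,
                                          xmax = .data$pct_high)) +
    ggplot2::labs(x = "percentage change in expected outcome",
                  y = NULL,
                  title = "Control-function second stage: percentage effects") +
    ggplot2::theme_minimal()
}

#' Histogram of generalized residuals
#'
#' Diagnostic view of the control-function term, split by exposure class; the
#' residuals are positive for exposed and negative for unexposed rows by
#' construction, and average to zero at the probit MLE.
#'
#' @param fit A `cf_2sri_fit`.
#' @return A ggplot object.
#' @export
plot_residual_distribution <- function(fit) {
  stopifnot(inherits(fit, "cf_2sri_fit"))
  df <- tibble::tibble(
    gen_resid = fit$residuals,
    exposure = factor(fit$first_stage$y)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gen_resid,
                                   fill = .data$exposure)) +
    ggplot2::geom_histogram(bins = 60, position = "identity", alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "generalized residual", y = "count", fill = "exposure",
                  title = "Control-function residuals by exposure class") +
    ggplot2::theme_minimal()
}
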