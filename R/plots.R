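#' Plot an age log-likelihood profile
#'
#' Shows the flat-prior posterior over the age grid with the
#' maximum-likelihood age marked.
#'
#' @param object An `age_likelihood`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot age_likelihood
#' @export
autoplot.age_likelihood <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$posterior)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_vline(xintercept = object$mle_age, linetype = 2) +
    ggplot2::labs(
      x = "Age (years)", y = "Posterior (flat prior)",
      title = sprintf("Sample %s: epigenetic age %g yr",
                      object$sample_id, object$mle_age)
    ) +
    ggplot2::theme_minimal()
}

#' Plot reference methylation-age trend curves
#'
#' One panel per site (top-ranked first), expected methylation against
#' grid age, annotated with the Spearman score.
#'
#' @param object An `age_reference`.
#' @param n_sites Number of top sites to show (default up to 16).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot age_reference
#' @export
autoplot.age_reference <- function(object, n_sites = 16, ...) {
  df <- tidy(object)
  df <- df[df$rank <= n_sites, ]
  df$panel <- sprintf("%s:%d (rho=%.2f)", df$chrom, df$pos, df$rho)
  df$panel <- factor(df$panel, levels = unique(df$panel))
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$expected_meth)) +
    ggplot2::geom_line(colour = "#d95f6e") +
    ggplot2::facet_wrap(~panel) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Age (years)", y = "Expected methylation") +
    ggplot2::theme_minimal()
}

#' Plot cross-validation results
#'
#' Predicted versus true age (`which = "scatter"`) or residuals versus
#' true age with the residual LOWESS trend (`which = "residuals"`).
#'
#' @param object A `cv_report`.
#' @param which `"scatter"` or `"residuals"`.
#' @param tau_resid LOWESS fraction for the residual trend panel.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, which = c("scatter", "residuals"),
                               tau_resid = 0.9, ...) {
  which <- match.arg(which)
  s <- tidy(object)
  s <- s[is.finite(s$mle_age), ]
  if (which == "scatter") {
    g <- glance(object)
    return(
      ggplot2::ggplot(s, ggplot2::aes(.data$true_age, .data$mle_age)) +
        ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
        ggplot2::geom_point(alpha = 0.6, colour = "#2c7fb8") +
        ggplot2::labs(
          x = "Chronological age (years)", y = "Epigenetic age (years)",
          title = sprintf("R2 = %.2f, MAE = %.1f yr", g$r_squared, g$mae)
        ) +
        ggplot2::theme_minimal()
    )
  }
  bias <- residual_bias(object, tau_resid = tau_resid)
  ggplot2::ggplot(s, ggplot2::aes(.data$true_age, .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.5, colour = "#2c7fb8") +
    ggplot2::geom_line(
      data = bias$trend,
      ggplot2::aes(.data$age, .data$residual_trend),
      colour = "#d95f6e", linewidth = 1
    ) +
    ggplot2::labs(
      x = "Chronological age (years)",
      y = "Residual (predicted - true, years)",
      title = sprintf("Residual-age Spearman = %.2f",
                      bias$residual_age_spearman)
    ) +
    ggplot2::theme_minimal()
}
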