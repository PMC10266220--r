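#' Violin plot of MTS by treatment group
#'
#' @param mts data.frame `sample_id, mts`.
#' @param samples sample sheet with `treated`.
#' @return a ggplot object.
#' @export
plot_mts_violin <- function(mts, samples) {
  tr <- samples$treated[match(mts$sample_id, samples$sample_id)]
  d <- data.frame(group = ifelse(tr == 1, "treated", "untreated"),
                  mts = mts$mts)
  ggplot2::ggplot(d, ggplot2::aes(x = group, y = mts,
                                  fill = group)) +
    ggplot2::geom_violin(trim = FALSE, alpha = 0.7) +
    ggplot2::geom_jitter(width = 0.08, size = 0.6, alpha = 0.5) +
    ggplot2::scale_fill_manual(values = c(treated = "#E69F00",
                                          untreated = "#56B4E9"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "methylation treatment score") +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param scores,labels as in [auc_rank()].
#' @return a ggplot object annotated with the rank-based AUC.
#' @export
plot_roc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  a <- auc_rank(scores, labels)
  ggplot2::ggplot(pts, ggplot2::aes(x = fpr, y = tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = 0.7, y = 0.1,
                      label = sprintf("AUC = %.2f", a)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate") +
    ggplot2::theme_minimal()
}

#' Time-since-treatment scatter with the therapeutic-lag annotation
#'
#' Treated samples' scores against days since first treatment (log10 axis)
#' with the fitted line and a dotted vertical line at the cited average
#' therapeutic lag for IFN-beta 1b (88.2 days, an annotation constant, not a
#' computed quantity).
#'
#' @param fit a `time_model_fit` from [fit_time_model()].
#' @param lag_days annotation line position (default 88.2).
#' @return a ggplot object.
#' @export
plot_time_model <- function(fit, lag_days = 88.2) {
  d <- fit$data
  ggplot2::ggplot(d, ggplot2::aes(x = days, y = mts)) +
    ggplot2::geom_point(colour = "#2c5aa0", alpha = 0.7) +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         colour = "red") +
    ggplot2::geom_vline(xintercept = lag_days, linetype = "dotted",
                        colour = "blue") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "days since first treatment",
                  y = "methylation treatment score",
                  subtitle = sprintf("slope %.3f/decade, R² = %.3f, p = %.3g",
                                     fit$slope, fit$r_squared, fit$p_value)) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("group", "mts", "fpr", "tpr", "days"))
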