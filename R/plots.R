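#' Violin plot of composite scores by group
#'
#' @param object A `score_report`.
#' @param ... Unused.
#' @return A ggplot object: score distributions per group, annotated with
#'   ROC-AUC and the Welch p-value.
#' @export
autoplot.score_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$score,
                                  fill = .data$group)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_jitter(width = 0.08, size = 1, alpha = 0.7,
                         show.legend = FALSE) +
    ggplot2::labs(
      title = sprintf("Composite score: %s", object$signature_name),
      subtitle = sprintf("ROC-AUC = %.3f, Welch p = %.3g (positive: %s)",
                         object$auc, object$p, object$positive),
      x = object$group_field, y = "composite score"
    ) +
    ggplot2::theme_minimal()
}

#' Step-fit diagnostic plot
#'
#' @param object A `step_fit` from [fit_step()].
#' @param ... Unused.
#' @return A ggplot object showing the series, the fitted step, and the
#'   threshold.
#' @export
autoplot.step_fit <- function(object, ...) {
  d <- tibble::tibble(index = seq_len(object$n), fitted = object$fitted)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$index)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$fitted), color = "firebrick") +
    ggplot2::geom_hline(yintercept = object$sthr, linetype = "dashed") +
    ggplot2::labs(
      title = if (object$no_step) "No step (constant series)" else
        sprintf("Step at k = %d, sthr = %.3g", object$k, object$sthr),
      x = "rank", y = "fitted value"
    ) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curve plot
#'
#' @param km A tibble from [km_estimate()] (optionally grouped).
#' @return A ggplot object with right-continuous survival steps.
#' @export
plot_km <- function(km) {
  stopifnot(all(c("time", "surv") %in% names(km)))
  has_group <- "group" %in% names(km)
  base <- tibble::tibble(
    group = if (has_group) unique(km$group) else "all",
    time = 0, surv = 1
  )
  d <- dplyr::bind_rows(
    base,
    if (has_group) km else dplyr::mutate(km, group = "all")
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$surv,
                                  color = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "S(t)", color = NULL) +
    ggplot2::theme_minimal()
}
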