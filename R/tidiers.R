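#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an RM-ANOVA result
#'
#' @param x An `rm_anova_result`.
#' @param ... Unused.
#' @return The effects tibble (one row per effect / contrast): `effect`,
#'   `df_num`, `df_den`, `statistic` (F), `p_value`, `partial_eta_sq`.
#' @export
tidy.rm_anova_result <- function(x, ...) x$effects

#' @rdname tidy.rm_anova_result
#' @return For `glance()`: a one-row tibble with the subject count and the
#'   smallest effect p-value.
#' @export
glance.rm_anova_result <- function(x, ...) {
  tibble(n_subjects = length(unique(x$data$subject)),
         n_effects = nrow(x$effects),
         min_p_value = min(x$effects$p_value, na.rm = TRUE))
}

#' Tidy an experiment report
#'
#' @param x An `experiment_report`.
#' @param ... Unused.
#' @return The group-level table: one row per classification x ROI x
#'   hemisphere with mean accuracy, SEM, t, one-tailed p and FDR flag.
#' @export
tidy.experiment_report <- function(x, ...) x$group

#' @rdname tidy.experiment_report
#' @export
glance.experiment_report <- function(x, ...) {
  tibble(n_subjects = x$config$n_subjects,
         n_cells = nrow(x$decoding),
         n_classifications = length(unique(x$decoding$classification)),
         mean_accuracy = mean(x$decoding$accuracy),
         n_fdr_significant = sum(x$group$fdr_rejected),
         seed = x$seed)
}

#' Plot group decoding accuracy by ROI and hemisphere
#'
#' Mean accuracy with +/- 1 SEM error bars per ROI and hemisphere, faceted
#' by classification, with the 0.5 chance level marked. FDR-significant
#' cells are drawn as solid points.
#'
#' @param object An `experiment_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.experiment_report <- function(object, ...) {
  g <- object$group
  ggplot2::ggplot(g, ggplot2::aes(x = .data$roi, y = .data$mean_accuracy,
                                  colour = .data$hemisphere,
                                  shape = .data$fdr_rejected)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_accuracy - .data$sem,
                   ymax = .data$mean_accuracy + .data$sem),
      position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "FDR significant") +
    ggplot2::facet_wrap(~classification) +
    ggplot2::labs(x = NULL, y = "Decoding accuracy",
                  colour = "Hemisphere") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a simulated design's condition regressors
#'
#' @param events Event table from [generate_design()].
#' @param spec The matching [design_spec()].
#' @param hrf An [hrf_model()].
#' @return A ggplot object: HRF-convolved condition time courses per run.
#' @export
plot_design <- function(events, spec, hrf = hrf_model()) {
  regs <- condition_regressors(events, spec, hrf)
  tb <- purrr::imap(regs, function(S, r) {
    as_tibble(as.data.frame(S)) |>
      dplyr::mutate(run = r, time = (dplyr::row_number() - 1) * spec$tr) |>
      tidyr::pivot_longer(-c("run", "time"), names_to = "condition",
                          values_to = "signal")
  }) |>
    dplyr::bind_rows()
  ggplot2::ggplot(tb, ggplot2::aes(.data$time, .data$signal,
                                   colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~run, ncol = 1, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Time (s)", y = "Model BOLD response") +
    ggplot2::theme_minimal()
}
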