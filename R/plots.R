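#' Heatmap of a channel-pair correlation matrix
#'
#' Tiles the Pearson matrix; pairs inside the spurious band
#' `[-threshold, threshold]` are greyed out.
#'
#' @param object an `fc_result`.
#' @param ... ignored.
#' @return a ggplot.
#' @method autoplot fc_result
#' @export
autoplot.fc_result <- function(object, ...) {
  r <- object$r
  df <- as_tibble(as.table(r), .name_repair = ~ c("from", "to", "r"))
  df$r[df$from == df$to] <- NA
  df$spurious <- !is.na(df$r) & abs(df$r) <= object$threshold
  ggplot2::ggplot(df, ggplot2::aes(x = .data$from, y = .data$to)) +
    ggplot2::geom_tile(ggplot2::aes(fill = ifelse(.data$spurious, NA, .data$r))) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1),
                                  na.value = "grey85", name = "r") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Functional connectivity (|r| > %.3f retained)",
                                  object$threshold)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Group x sex activation summary plot
#'
#' Mean baseline-corrected HbO per region with standard-error bars,
#' faceted by interaction.
#'
#' @param activation tibble from [roi_activation_table()] (with `group`
#'   and `sex` columns); rows flagged `outlier` are dropped if present.
#' @return a ggplot.
#' @export
plot_activation <- function(activation) {
  if ("outlier" %in% names(activation)) {
    activation <- activation[!activation$outlier, ]
  }
  summ <- activation |>
    dplyr::filter(!is.na(.data$mean_dHbO)) |>
    dplyr::group_by(.data$interaction, .data$roi, .data$group, .data$sex) |>
    dplyr::summarise(m = mean(.data$mean_dHbO),
                     se = sd(.data$mean_dHbO) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$roi, y = .data$m,
                                     fill = interaction(.data$group, .data$sex))) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$m - .data$se, ymax = .data$m + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.25
    ) +
    ggplot2::facet_wrap(~interaction) +
    ggplot2::labs(x = "region", y = "mean dHbO (uM)", fill = "group.sex") +
    ggplot2::theme_minimal()
}

#' Connection-count summary plot
#'
#' Non-spurious connection counts within the motor block, within the
#' frontal block, and between blocks, by group and sex.
#'
#' @param connections tibble from [run_pipeline()] (`$connections`).
#' @return a ggplot.
#' @export
plot_connection_counts <- function(connections) {
  long <- connections |>
    tidyr::pivot_longer(c("within_motor", "within_frontal", "between"),
                        names_to = "block", values_to = "count")
  summ <- long |>
    dplyr::group_by(.data$block, .data$group, .data$sex) |>
    dplyr::summarise(m = mean(.data$count),
                     se = sd(.data$count) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$block, y = .data$m,
                                     fill = .data$sex,
                                     alpha = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$m - .data$se, ymax = .data$m + .data$se),
      position = ggplot2::position_dodge(0.8), width = 0.25
    ) +
    ggplot2::scale_alpha_manual(values = c(0.55, 1)) +
    ggplot2::labs(x = NULL, y = "non-spurious connections") +
    ggplot2::theme_minimal()
}

#' Graph-metric distributions by group and sex
#'
#' @param metrics tibble from [run_pipeline()] (`$metrics`).
#' @return a ggplot.
#' @export
plot_graph_metrics <- function(metrics) {
  long <- metrics |>
    tidyr::pivot_longer(c("global_efficiency", "local_efficiency",
                          "clustering_coefficient", "modularity"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sex, y = .data$value,
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_connection_counts autoplot method for a full run:
#'   connection counts panel.
#' @param object a `pipeline_run`.
#' @param ... ignored.
#' @method autoplot pipeline_run
#' @export
autoplot.pipeline_run <- function(object, ...) {
  plot_connection_counts(object$connections)
}
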