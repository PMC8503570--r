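#' Boxplots of estimated atrophy across Monte Carlo transforms
#'
#' For every subject and transform, the estimated CSA at scaling `r` is
#' divided by the same subject's mean unscaled CSA; boxplots of these ratios
#' (as remaining CSA, %) are drawn per simulated atrophy with the ground
#' truth `100 r^2` overlaid.
#'
#' @param records CSA record tibble (see [intra_subject_stats()]).
#' @return A ggplot object.
#' @export
plot_atrophy_recovery <- function(records) {
  check_records(records)
  base <- records |>
    dplyr::filter(.data$scaling_r == 1) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(csa_unscaled = mean(.data$mean_csa_mm2),
                     .groups = "drop")
  df <- records |>
    dplyr::inner_join(base, by = "subject_id") |>
    dplyr::mutate(
      remaining_pct = 100 * .data$mean_csa_mm2 / .data$csa_unscaled,
      atrophy = factor(sprintf("%.2f", atrophy_percent(.data$scaling_r))))
  truth <- df |>
    dplyr::distinct(.data$atrophy, .data$scaling_r) |>
    dplyr::mutate(truth_pct = 100 * .data$scaling_r^2)
  ggplot2::ggplot(df, ggplot2::aes(.data$atrophy, .data$remaining_pct)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_point(data = truth,
                        ggplot2::aes(.data$atrophy, .data$truth_pct),
                        color = "red", shape = 4, size = 2) +
    ggplot2::labs(x = "simulated atrophy (%)",
                  y = "estimated CSA relative to unscaled (%)")
}

#' Minimum sample size versus atrophy
#'
#' Log-scale curves of the minimum sample size per study arm against the
#' simulated atrophy, by contrast, faceted by design and power, with Monte
#' Carlo error bars where available.
#'
#' @param sample_sizes The `sample_sizes` tibble of a [run_pipeline()]
#'   bundle.
#' @return A ggplot object.
#' @export
plot_sample_size <- function(sample_sizes) {
  df <- dplyr::mutate(sample_sizes,
                      setting = sprintf("%s, %d%% power", .data$design,
                                        round(100 * .data$power)))
  ggplot2::ggplot(df, ggplot2::aes(.data$atrophy_percent, .data$mc_mean,
                                   color = .data$contrast)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mc_mean - .data$mc_sd,
                                        ymax = .data$mc_mean + .data$mc_sd),
                           width = 0.1) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~setting, scales = "free_y") +
    ggplot2::labs(x = "simulated atrophy (%)",
                  y = "minimum sample size per arm")
}
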