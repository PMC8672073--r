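#' Light-potential scatter diagnostics
#'
#' Plots a derived parameter against sqrt(ambient PAR), coloured by leaf
#' temperature — the standard presentation for field light-response
#' surveys (sqrt(PAR) resolves the low-light range and partially
#' linearizes the responses).
#'
#' @param records Derived-record tibble from [derive_parameters()].
#' @param param Column name to plot (e.g. `"lef_amb"`,
#'   `"npqt_high_amb"`).
#' @param colour Colour variable (default `t_leaf`).
#' @return A ggplot object.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_leaves = 30, seed = 2))
#' rec <- derive_parameters(sim$measurements)
#' plot_light_potential(rec, "npqt_high_amb")
plot_light_potential <- function(records, param, colour = "t_leaf") {
  if (!param %in% names(records)) {
    abort(sprintf("column '%s' not found", param))
  }
  ggplot2::ggplot(records, ggplot2::aes(x = .data$sqrt_par,
                                        y = .data[[param]],
                                        colour = .data[[colour]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = expression(sqrt(PAR[amb])), y = param) +
    ggplot2::theme_minimal()
}

#' Per-cluster NPQ-vs-pmf slope diagnostics
#'
#' Scatter of rapidly induced NPQ against the rapid pmf change with one
#' fitted regression line per cluster.
#'
#' @param records Derived-record tibble.
#' @param assignments Integer cluster labels.
#' @return A ggplot object.
#' @export
plot_cluster_slopes <- function(records, assignments) {
  df <- records
  df$cluster <- factor(assignments)
  df <- df[!is.na(df$cluster) & is.finite(df$ecst_high_amb) &
             is.finite(df$npqt_high_amb), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ecst_high_amb,
                                   y = .data$npqt_high_amb,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "ECSt (high - amb)", y = "NPQt (high - amb)") +
    ggplot2::theme_minimal()
}
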