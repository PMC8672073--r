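lp_mechanism_labels <- function() {
  c(Model1 = "Model1_PSI_acceptor", Model2 = "Model2_NPQ",
    Model3 = "Model3_PCON", Intermediate = "Intermediate")
}

#' Classify the mechanistic limitation from light-potential signs
#'
#' Upon a step to full-sunlight-equivalent PAR, the three candidate
#' limitations predict distinct sign patterns of the light-induced changes
#' in QA redox state (`qL_high_amb`) and P700 oxidation
#' (`p700_high_amb`):
#' \describe{
#'   \item{Model 1 (PSI acceptor-side limitation)}{net reduction of both:
#'     `p700_high_amb < 0` and `ql_high_amb < 0`.}
#'   \item{Model 2 (rapid NPQ)}{net oxidation of both:
#'     `p700_high_amb > 0` and `ql_high_amb > 0`.}
#'   \item{Model 3 (photosynthetic control)}{net oxidation of P700 but
#'     net reduction of QA: `p700_high_amb > 0` and `ql_high_amb < 0`.}
#' }
#' Points inside the dead-zone `margin` around zero, in the fourth
#' quadrant (which no model predicts), or with missing evidence are
#' labelled `Intermediate`.
#'
#' @param ql_diff,p700_diff Numeric vectors of light-induced changes
#'   (`X_high - X_amb`).
#' @param margin Non-negative dead-zone half-width around zero.
#' @return Character vector of labels `Model1_PSI_acceptor`, `Model2_NPQ`,
#'   `Model3_PCON`, or `Intermediate`.
#' @export
#' @examples
#' classify_point(-0.2, 0.1)   # Model3_PCON
#' classify_point(0.2, 0.1)    # Model2_NPQ
#' classify_point(0, 0, margin = 0.02)
classify_point <- function(ql_diff, p700_diff, margin = 0) {
  stopifnot(margin >= 0)
  lab <- lp_mechanism_labels()
  out <- rep(lab[["Intermediate"]], max(length(ql_diff), length(p700_diff)))
  ql_diff <- rep_len(ql_diff, length(out))
  p700_diff <- rep_len(p700_diff, length(out))
  ok <- is.finite(ql_diff) & is.finite(p700_diff)
  out[ok & p700_diff < -margin & ql_diff < -margin] <- lab[["Model1"]]
  out[ok & p700_diff > margin & ql_diff > margin] <- lab[["Model2"]]
  out[ok & p700_diff > margin & ql_diff < -margin] <- lab[["Model3"]]
  out
}

#' @rdname classify_point
#' @param records Derived-record tibble with `ql_high_amb` and
#'   `p700_high_amb` columns (see [derive_parameters()]).
#' @return For `classify_mechanism()`, the input tibble with a
#'   `mechanism` column appended.
#' @export
classify_mechanism <- function(records, margin = 0) {
  need <- c("ql_high_amb", "p700_high_amb")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort(paste0("missing columns: ",
                                 paste(miss, collapse = ", ")))
  records$mechanism <- classify_point(records$ql_high_amb,
                                      records$p700_high_amb, margin)
  records
}

#' Per-cluster sensitivity of rapid NPQ to the rapid pmf change
#'
#' Within each cluster, the OLS slope (with intercept) of `npqt_high_amb`
#' on `ecst_high_amb` — the rapidly inducible qE response per unit
#' light-induced proton motive force. Small slopes indicate suppression of
#' qE despite lumen acidification (photosynthetic-control behaviour).
#'
#' @param records Derived-record tibble with `npqt_high_amb` and
#'   `ecst_high_amb`.
#' @param assignments Integer cluster labels, length `nrow(records)`
#'   (`NA` ignored).
#' @param min_n Minimum usable rows per cluster; below it (or with zero
#'   variance in `ecst_high_amb`) the slope is inestimable.
#' @return A tibble: `cluster`, `slope`, `slope_se`, `intercept`, `n`,
#'   `note`.
#' @export
cluster_slopes <- function(records, assignments, min_n = 3L) {
  stopifnot(length(assignments) == nrow(records))
  need <- c("npqt_high_amb", "ecst_high_amb")
  miss <- setdiff(need, names(records))
  if (length(miss)) abort(paste0("missing columns: ",
                                 paste(miss, collapse = ", ")))
  clusters <- sort(unique(assignments[!is.na(assignments)]))
  purrr::map_dfr(clusters, function(k) {
    rows <- which(assignments == k)
    x <- records$ecst_high_amb[rows]; y <- records$npqt_high_amb[rows]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < min_n || sd(x) == 0) {
      return(tibble::tibble(cluster = k, slope = NA_real_,
                            slope_se = NA_real_, intercept = NA_real_,
                            n = length(x), note = "inestimable"))
    }
    fit <- lm(y ~ x)
    sm <- summary(fit)$coefficients
    tibble::tibble(cluster = k, slope = sm["x", 1], slope_se = sm["x", 2],
                   intercept = sm["(Intercept)", 1], n = length(x),
                   note = NA_character_)
  })
}

#' Mechanistic report over a clustering
#'
#' Combines point-level mechanistic classification with a cluster
#' configuration (typically a GMM over `ql_high_amb`, `p700_high_amb`,
#' `t_leaf`): per-cluster majority label, the fraction of points in each
#' model's sign region, environmental summaries (median and IQR of
#' `t_leaf` and `sqrt_par`), and the per-cluster NPQ-vs-pmf slopes.
#'
#' @param records Derived-record tibble.
#' @param assignments Integer cluster labels, length `nrow(records)`.
#' @param margin Dead-zone margin for [classify_point()].
#' @return An object of class `lp_mechanism_report`: a list with
#'   `$points` (records + `mechanism` + `cluster`), `$clusters`
#'   (per-cluster table), and `$slopes` (from [cluster_slopes()]).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_leaves = 40, seed = 5))
#' rec <- derive_parameters(sim$measurements)
#' rep <- mechanism_report(rec, rep(1L, nrow(rec)))
#' rep$clusters
mechanism_report <- function(records, assignments, margin = 0) {
  stopifnot(length(assignments) == nrow(records))
  pts <- classify_mechanism(records, margin)
  pts$cluster <- assignments
  lab <- lp_mechanism_labels()

  has_slopes <- all(c("npqt_high_amb", "ecst_high_amb") %in% names(records))
  slopes <- if (has_slopes) cluster_slopes(records, assignments) else NULL

  clusters <- pts |>
    dplyr::filter(!is.na(.data$cluster)) |>
    dplyr::group_by(cluster = .data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      majority_label = names(sort(table(.data$mechanism),
                                  decreasing = TRUE))[1],
      frac_model1 = mean(.data$mechanism == lab[["Model1"]]),
      frac_model2 = mean(.data$mechanism == lab[["Model2"]]),
      frac_model3 = mean(.data$mechanism == lab[["Model3"]]),
      frac_intermediate = mean(.data$mechanism == lab[["Intermediate"]]),
      t_leaf_median = median(.data$t_leaf, na.rm = TRUE),
      t_leaf_iqr = stats::IQR(.data$t_leaf, na.rm = TRUE),
      sqrt_par_median = median(.data$sqrt_par, na.rm = TRUE),
      sqrt_par_iqr = stats::IQR(.data$sqrt_par, na.rm = TRUE),
      .groups = "drop")
  if (!is.null(slopes)) {
    clusters <- dplyr::left_join(clusters,
                                 slopes[c("cluster", "slope", "slope_se")],
                                 by = "cluster")
  }
  structure(list(points = pts, clusters = clusters, slopes = slopes,
                 margin = margin),
            class = "lp_mechanism_report")
}

#' @export
print.lp_mechanism_report <- function(x, ...) {
  cat("<lp_mechanism_report> (margin = ", x$margin, ")\n", sep = "")
  print(x$clusters)
  invisible(x)
}

#' @export
tidy.lp_mechanism_report <- function(x, ...) x$clusters

#' Diagnostic plot of the mechanistic evidence plane
#'
#' Scatter of `ql_high_amb` against `p700_high_amb` with the model sign
#' regions marked, coloured by cluster when assignments are available.
#'
#' @param object An `lp_mechanism_report`.
#' @param ... Unused.
#' @export
autoplot.lp_mechanism_report <- function(object, ...) {
  df <- object$points
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$ql_high_amb,
                                        y = .data$p700_high_amb))
  if (!all(is.na(df$cluster))) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$cluster)),
                                 alpha = 0.7) +
      ggplot2::labs(colour = "cluster")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p + ggplot2::geom_hline(yintercept = c(-1, 1) * object$margin,
                          linetype = "dashed") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * object$margin,
                        linetype = "dashed") +
    ggplot2::labs(x = "qL (high - amb)", y = "P700+ (high - amb)") +
    ggplot2::theme_minimal()
}
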