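#' Per-cluster covariate dependence of a response
#'
#' Ordinary least squares of the response on the covariates within each
#' cluster, reporting coefficients, standard errors, two-sided p-values
#' and a significance call at `alpha`. Clusters with fewer than `min_n`
#' usable rows are reported as untestable; a zero-variance response gives
#' zero coefficients with a `zero_variance` note; rank-deficient designs
#' mark the dropped coefficients `inestimable`.
#'
#' @param data Analysis tibble.
#' @param assignments Integer cluster labels, length `nrow(data)` (`NA`
#'   rows are ignored).
#' @param response,covariates Column names.
#' @param alpha Two-sided significance level.
#' @param min_n Minimum cluster size for testing.
#' @return A tibble with columns `cluster`, `term`, `estimate`,
#'   `std_error`, `statistic`, `p_value`, `significant`, `n`, `note`.
#' @export
#' @examples
#' d <- tibble::tibble(y = 3 * (1:40) + rnorm(40), x = 1:40,
#'                     t_leaf = rnorm(40, 25))
#' within_cluster_dependence(d, rep(1L, 40), "y", c("x", "t_leaf"))
within_cluster_dependence <- function(data, assignments, response,
                                      covariates, alpha = 0.05, min_n = 5L) {
  stopifnot(length(assignments) == nrow(data))
  clusters <- sort(unique(assignments[!is.na(assignments)]))
  purrr::map_dfr(clusters, function(k) {
    rows <- which(assignments == k)
    sub <- data[rows, c(response, covariates), drop = FALSE]
    sub <- sub[complete.cases(sub), , drop = FALSE]
    n_k <- nrow(sub)
    base <- tibble::tibble(cluster = k,
                           term = c("(Intercept)", covariates),
                           estimate = NA_real_, std_error = NA_real_,
                           statistic = NA_real_, p_value = NA_real_,
                           significant = NA, n = n_k, note = NA_character_)
    if (n_k < min_n) {
      base$note <- "untestable"
      return(base)
    }
    y <- sub[[response]]
    if (sd(y) == 0) {
      base$estimate <- c(y[1], rep(0, length(covariates)))
      base$note <- "zero_variance"
      return(base)
    }
    f <- stats::reformulate(covariates, response = response)
    fit <- lm(f, data = sub)
    sm <- summary(fit)$coefficients
    for (i in seq_len(nrow(base))) {
      tm <- base$term[i]
      if (tm %in% rownames(sm)) {
        base$estimate[i] <- sm[tm, 1]; base$std_error[i] <- sm[tm, 2]
        base$statistic[i] <- sm[tm, 3]; base$p_value[i] <- sm[tm, 4]
        base$significant[i] <- sm[tm, 4] < alpha
      } else {
        base$note[i] <- "inestimable"
      }
    }
    base
  })
}

#' Global linear-effects model
#'
#' OLS of a response on sqrt(ambient PAR), leaf temperature and their
#' interaction over the whole analysis table — the simple whole-dataset
#' model the cluster analysis refines.
#'
#' @param data Analysis tibble with >= 10 rows.
#' @param response Response column name.
#' @param covariates Length-2 character vector of main-effect columns.
#' @return Object of class `lp_linear_effects`, with [tidy()] and
#'   [glance()] methods.
#' @export
fit_linear_effects <- function(data, response,
                               covariates = c("sqrt_par", "t_leaf")) {
  stopifnot(length(covariates) == 2L)
  cols <- c(response, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) abort(paste0("columns not found: ",
                                 paste(miss, collapse = ", ")))
  sub <- data[cols]
  sub <- sub[complete.cases(sub), , drop = FALSE]
  if (nrow(sub) < 10L) abort("need >= 10 usable rows.")
  f <- stats::as.formula(paste(response, "~", covariates[1], "*",
                               covariates[2]))
  fit <- lm(f, data = sub)
  structure(list(model = fit, response = response, covariates = covariates,
                 n = nrow(sub)),
            class = "lp_linear_effects")
}

#' @export
print.lp_linear_effects <- function(x, ...) {
  cat("<lp_linear_effects> ", x$response, " ~ ", x$covariates[1], " * ",
      x$covariates[2], " (n = ", x$n, ")\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.lp_linear_effects <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                 std_error = sm[, 2], statistic = sm[, 3],
                 p_value = sm[, 4])
}

#' @export
glance.lp_linear_effects <- function(x, ...) {
  sm <- summary(x$model)
  tibble::tibble(r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
                 sigma = sm$sigma, n = x$n)
}

#' Subsample robustness of a GMM clustering
#'
#' Refits the mixture on random subsamples and compares each refit to the
#' full-data clustering (restricted to the subsampled rows) with the
#' adjusted Rand index, recording the selected number of components — a
#' first-order check that the cluster structure is not an artefact of any
#' particular subset of the data.
#'
#' @param data Analysis tibble.
#' @param response,covariates,K,families,n_init,standardize Passed to
#'   [fit_gmm()].
#' @param fractions Subsample fractions in (0, 1].
#' @param n_reps Replicates per fraction.
#' @param seed Integer seed controlling both the full fit and subsampling.
#' @param min_rows Subsamples smaller than this are skipped with a note.
#' @return A tibble with one row per (fraction, rep): `fraction`, `rep`,
#'   `n`, `K`, `ari`, `skipped`. The full-data fit is attached as
#'   attribute `"full_fit"`.
#' @export
subsample_robustness <- function(data, response,
                                 covariates = c("sqrt_par", "t_leaf"),
                                 fractions = c(0.25, 0.5, 0.75),
                                 n_reps = 10, seed = 1, K = 1:6,
                                 families = lp_gmm_families(), n_init = 3,
                                 standardize = TRUE, min_rows = 10L) {
  if (any(fractions <= 0) || any(fractions > 1)) {
    abort("`fractions` must lie in (0, 1].")
  }
  full <- fit_gmm(data, response, covariates, K = K, families = families,
                  n_init = n_init, seed = seed, standardize = standardize)
  full_labels <- rep(NA_integer_, nrow(data))
  full_labels[full$row_index] <- full$assignments

  rows <- withr::with_seed(seed, {
    purrr::map_dfr(fractions, function(f) {
      purrr::map_dfr(seq_len(n_reps), function(r) {
        m <- round(f * nrow(data))
        idx <- sort(sample.int(nrow(data), m))
        if (m < min_rows) {
          return(tibble::tibble(fraction = f, rep = r, n = m,
                                K = NA_integer_, ari = NA_real_,
                                skipped = TRUE))
        }
        sub <- data[idx, , drop = FALSE]
        refit <- tryCatch(
          fit_gmm(sub, response, covariates, K = K, families = families,
                  n_init = n_init, seed = seed, standardize = standardize),
          error = function(e) NULL)
        if (is.null(refit)) {
          return(tibble::tibble(fraction = f, rep = r, n = m,
                                K = NA_integer_, ari = NA_real_,
                                skipped = TRUE))
        }
        sub_labels <- rep(NA_integer_, m)
        sub_labels[refit$row_index] <- refit$assignments
        ref <- full_labels[idx]
        ok <- !is.na(ref) & !is.na(sub_labels)
        tibble::tibble(fraction = f, rep = r, n = m, K = refit$K,
                       ari = mclust::adjustedRandIndex(ref[ok],
                                                       sub_labels[ok]),
                       skipped = FALSE)
      })
    })
  })
  attr(rows, "full_fit") <- full
  rows
}
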