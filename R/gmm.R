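#' Covariance families for the Gaussian mixture model
#'
#' Six parametrizations on a spherical/diagonal/full x equal/varying
#' lattice, ordered from simplest to most flexible. "Equal" families share
#' one covariance across components; "varying" families estimate one per
#' component.
#'
#' @return Character vector of family names.
#' @export
lp_gmm_families <- function() {
  c("spherical_equal", "spherical_varying",
    "diagonal_equal", "diagonal_varying",
    "full_equal", "full_varying")
}

cov_n_params <- function(family, K, d) {
  switch(family,
         spherical_equal = 1,
         spherical_varying = K,
         diagonal_equal = d,
         diagonal_varying = K * d,
         full_equal = d * (d + 1) / 2,
         full_varying = K * d * (d + 1) / 2,
         abort(sprintf("unknown covariance family '%s'", family)))
}

# component-wise multivariate normal log densities, n x K
log_dens_matrix <- function(X, means, covs) {
  K <- nrow(means); d <- ncol(X)
  out <- matrix(NA_real_, nrow(X), K)
  for (k in seq_len(K)) {
    ch <- chol(covs[[k]])
    z <- forwardsolve(t(ch), t(X) - means[k, ])
    out[, k] <- -0.5 * d * log(2 * pi) - sum(log(diag(ch))) -
      0.5 * colSums(z^2)
  }
  out
}

# k-means++ style seeding: distance-weighted center picks from the data
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  idx <- sample.int(n, 1L)
  centers[1, ] <- X[idx, ]
  if (K > 1L) {
    d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
    for (k in 2:K) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1L, prob = prob)
      centers[k, ] <- X[idx, ]
      d2 <- pmin(d2, rowSums((X - matrix(centers[k, ], n, ncol(X),
                                         byrow = TRUE))^2))
    }
  }
  centers
}

m_step_cov <- function(X, resp, means, family, ridge) {
  K <- ncol(resp); d <- ncol(X); n <- nrow(X)
  nk <- colSums(resp)
  Sk <- vector("list", K)
  for (k in seq_len(K)) {
    Xc <- X - matrix(means[k, ], n, d, byrow = TRUE)
    Sk[[k]] <- crossprod(Xc * resp[, k], Xc) / nk[k]
  }
  equal <- endsWith(family, "_equal")
  if (equal) {
    S <- Sk[[1]] * nk[1]
    if (K > 1) for (k in 2:K) S <- S + Sk[[k]] * nk[k]
    S <- S / n
    Sk <- rep(list(S), K)
  }
  shape <- substr(family, 1, 4) # "sphe", "diag", "full"
  ridge_mat <- diag(ridge, d)
  shape_one <- function(S) {
    if (shape == "diag") S <- diag(diag(S), d)
    else if (shape == "sphe") S <- diag(rep(mean(diag(S)), d), d)
    S + ridge_mat
  }
  if (equal) rep(list(shape_one(Sk[[1]])), K) else lapply(Sk, shape_one)
}

# Guard against the classic mixture-likelihood pathology: a component
# collapsing onto a handful of points with vanishing variance. Solutions
# with an effective component size below d + 1 or a covariance eigenvalue
# below `var_floor` (on the standardized feature scale) are rejected.
degenerate_fit <- function(covs, nk, d, var_floor) {
  if (any(nk < d + 1)) return(TRUE)
  min_eig <- min(vapply(covs, function(S) min(eigen(S, symmetric = TRUE,
                                                    only.values = TRUE)$values),
                        numeric(1)))
  min_eig < var_floor
}

run_em <- function(X, K, family, centers, ridge, tol, max_iter,
                   var_floor = 1e-4) {
  n <- nrow(X); d <- ncol(X)
  # Lloyd refinement of the seeded centers gives balanced starting
  # partitions (raw k-means++ seeds gravitate to outlying points)
  km <- tryCatch(suppressWarnings(
    kmeans(X, centers = centers, iter.max = 20, algorithm = "Lloyd")),
    error = function(e) NULL)
  assign0 <- if (!is.null(km) && length(unique(km$cluster)) == K) {
    km$cluster
  } else {
    d2 <- vapply(seq_len(K), function(k) {
      rowSums((X - matrix(centers[k, ], n, d, byrow = TRUE))^2)
    }, numeric(n))
    max.col(-matrix(d2, n, K), ties.method = "first")
  }
  resp <- matrix(0, n, K); resp[cbind(seq_len(n), assign0)] <- 1
  nk <- colSums(resp)
  if (any(nk < 1)) return(NULL)
  weights <- nk / n
  means <- (t(resp) %*% X) / nk
  covs <- tryCatch(m_step_cov(X, resp, means, family, ridge),
                   error = function(e) NULL)
  if (is.null(covs)) return(NULL)

  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    ld <- tryCatch(log_dens_matrix(X, means, covs), error = function(e) NULL)
    if (is.null(ld) || any(!is.finite(ld))) return(NULL)
    lw <- ld + rep(log(weights), each = n)
    m <- lw[cbind(seq_len(n), max.col(lw, ties.method = "first"))]
    lse <- m + log(rowSums(exp(lw - m)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(lw - lse)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) break
    ll_old <- ll
    nk <- colSums(resp)
    if (any(nk < d + 1)) return(NULL) # component collapsing
    weights <- nk / n
    means <- (t(resp) %*% X) / nk
    covs <- tryCatch(m_step_cov(X, resp, means, family, ridge),
                     error = function(e) NULL)
    if (is.null(covs)) return(NULL)
  }
  if (degenerate_fit(covs, colSums(resp), d, var_floor)) return(NULL)
  list(weights = weights, means = means, covs = covs, resp = resp,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       iterations = length(ll_trace),
       converged = length(ll_trace) < max_iter)
}

#' Fit a Gaussian mixture model with EM and BIC model selection
#'
#' Fits mixtures of `K` Gaussian components over a feature set consisting
#' of one response plus environmental covariates, for every combination of
#' `K` and covariance family, each from `n_init` k-means++-style
#' initializations run to EM convergence. The model minimizing
#' `BIC = -2 * loglik + p * log(n)` is returned; ties prefer smaller `K`,
#' then the simpler family. Features are z-score standardized by default
#' (centers/scales are stored so cluster means can be reported on the
#' original scale). Fully deterministic given `seed`.
#'
#' @param data A tibble (e.g. from [derive_parameters()] + [apply_qc()]).
#' @param response Name of the response column.
#' @param covariates Covariate column names (default `sqrt_par`,
#'   `t_leaf`). Rows with a missing value in any feature are excluded and
#'   counted.
#' @param K Integer vector of component counts to try (within 1..12).
#' @param families Covariance families to try, see [lp_gmm_families()].
#' @param n_init Number of random initializations per candidate.
#' @param seed Integer seed.
#' @param standardize Z-score the features before EM?
#' @param ridge Diagonal regularization added to every covariance; if a
#'   candidate is still singular it is dropped with a warning.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return An object of class `lp_gmm`; see [tidy.lp_gmm()],
#'   [glance.lp_gmm()], [autoplot.lp_gmm()]. Clusters are relabelled by
#'   ascending cluster mean of `sqrt_par` (first feature otherwise).
#' @export
#' @examples
#' set.seed(1)
#' d <- tibble::tibble(
#'   y = c(rnorm(50), rnorm(50, 8)),
#'   sqrt_par = c(rnorm(50, 10), rnorm(50, 30)),
#'   t_leaf = rnorm(100, 25))
#' fit <- fit_gmm(d, "y", K = 1:3, n_init = 2, seed = 1)
#' glance(fit)
fit_gmm <- function(data, response, covariates = c("sqrt_par", "t_leaf"),
                    K = 1:8, families = lp_gmm_families(), n_init = 5,
                    seed = 1, standardize = TRUE, ridge = 1e-8,
                    tol = 1e-8, max_iter = 500) {
  cols <- c(response, covariates)
  miss <- setdiff(cols, names(data))
  if (length(miss)) abort(paste0("feature columns not found: ",
                                 paste(miss, collapse = ", ")))
  if (any(K < 1) || any(K > 12)) abort("`K` must lie within 1..12.")
  families <- match.arg(families, lp_gmm_families(), several.ok = TRUE)

  feat <- data[cols]
  ok <- complete.cases(feat)
  n_excluded <- sum(!ok)
  X0 <- as.matrix(feat[ok, , drop = FALSE])
  n <- nrow(X0); d <- ncol(X0)
  if (n < 10L) abort("need >= 10 usable rows to fit a mixture.")

  center <- if (standardize) colMeans(X0) else rep(0, d)
  scale_ <- if (standardize) apply(X0, 2, sd) else rep(1, d)
  if (any(scale_ == 0)) scale_[scale_ == 0] <- 1
  X <- sweep(sweep(X0, 2, center), 2, scale_, `/`)

  grid <- expand.grid(K = sort(unique(K)), family = families,
                      stringsAsFactors = FALSE)
  results <- vector("list", nrow(grid))
  bic_rows <- vector("list", nrow(grid))

  withr::with_seed(seed, {
    for (i in seq_len(nrow(grid))) {
      Ki <- grid$K[i]; fam <- grid$family[i]
      best <- NULL
      for (init in seq_len(n_init)) {
        centers <- kmeanspp_centers(X, Ki)
        em <- run_em(X, Ki, fam, centers, ridge, tol, max_iter)
        if (!is.null(em) && (is.null(best) || em$loglik > best$loglik)) {
          best <- em
        }
      }
      if (is.null(best)) {
        warn(sprintf("candidate K=%d family=%s dropped (singular/degenerate)",
                     Ki, fam))
        next
      }
      p <- (Ki - 1) + Ki * d + cov_n_params(fam, Ki, d)
      bic <- -2 * best$loglik + p * log(n)
      results[[i]] <- best
      bic_rows[[i]] <- tibble::tibble(K = Ki, family = fam,
                                      loglik = best$loglik, df = p,
                                      bic = bic,
                                      converged = best$converged)
    }
  })

  bic_table <- dplyr::bind_rows(bic_rows)
  if (nrow(bic_table) == 0L) abort("no mixture candidate could be fitted.")
  fitted_idx <- which(!vapply(bic_rows, is.null, logical(1)))
  # tie-break: min BIC, then smaller K, then simpler family (lattice order)
  fam_rank <- match(grid$family[fitted_idx], lp_gmm_families())
  ord <- order(bic_table$bic, bic_table$K, fam_rank)
  sel <- ord[1]
  best <- results[[fitted_idx[sel]]]
  sel_K <- bic_table$K[sel]; sel_fam <- bic_table$family[sel]

  # relabel clusters by ascending mean of sqrt_par (or the first feature)
  ord_col <- if ("sqrt_par" %in% cols) match("sqrt_par", cols) else 1L
  means_orig <- sweep(sweep(best$means, 2, scale_, `*`), 2, center, `+`)
  relab <- order(means_orig[, ord_col])
  weights <- best$weights[relab]
  means_orig <- means_orig[relab, , drop = FALSE]
  means_std <- best$means[relab, , drop = FALSE]
  covs_std <- best$covs[relab]
  resp <- best$resp[, relab, drop = FALSE]
  covs_orig <- purrr::map(covs_std, function(S) {
    diag(scale_, d) %*% S %*% diag(scale_, d)
  })
  colnames(means_orig) <- colnames(means_std) <- cols

  assignments <- max.col(resp, ties.method = "first")
  structure(list(
    K = sel_K, family = sel_fam, weights = weights,
    means = means_orig, means_std = means_std,
    covariances = covs_orig, covariances_std = covs_std,
    responsibilities = resp, assignments = assignments,
    loglik = best$loglik, loglik_trace = best$loglik_trace,
    iterations = best$iterations, converged = best$converged,
    bic = bic_table$bic[sel], bic_table = bic_table,
    response = response, covariates = covariates, features = cols,
    data = tibble::as_tibble(feat[ok, , drop = FALSE]),
    row_index = which(ok), n = n, n_input = nrow(data),
    n_excluded = n_excluded,
    center = center, scale = scale_, standardize = standardize,
    n_init = n_init, seed = seed
  ), class = "lp_gmm")
}

#' @export
print.lp_gmm <- function(x, ...) {
  cat("<lp_gmm> ", x$K, " components (", x$family, "), features: ",
      paste(x$features, collapse = ", "), "\n", sep = "")
  cat("  n = ", x$n, " (", x$n_excluded, " excluded), loglik = ",
      format(x$loglik), ", BIC = ", format(x$bic), "\n", sep = "")
  cat("  mixing weights:", format(round(x$weights, 3)), "\n")
  invisible(x)
}

#' Broom-style accessors for `lp_gmm` fits
#'
#' `tidy()` returns one row per cluster/feature pair with the mixing
#' weight, cluster mean and marginal SD on the original feature scale;
#' `glance()` returns a one-row model summary; `augment()` returns the
#' feature table used for fitting with `.cluster` and `.responsibility`
#' (the MAP posterior probability) columns.
#'
#' @param x,object An `lp_gmm` fit.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.lp_gmm <- function(x, ...) {
  purrr::map_dfr(seq_len(x$K), function(k) {
    tibble::tibble(cluster = k, weight = x$weights[k],
                   variable = x$features,
                   mean = x$means[k, ],
                   sd = sqrt(diag(x$covariances[[k]])))
  })
}

#' @rdname tidy.lp_gmm
#' @export
glance.lp_gmm <- function(x, ...) {
  tibble::tibble(K = x$K, family = x$family, loglik = x$loglik,
                 df = x$bic_table$df[x$bic_table$K == x$K &
                                       x$bic_table$family == x$family][1],
                 bic = x$bic, n = x$n, n_excluded = x$n_excluded,
                 iterations = x$iterations, converged = x$converged)
}

#' @rdname tidy.lp_gmm
#' @export
augment.lp_gmm <- function(x, ...) {
  out <- x$data
  out$.cluster <- factor(x$assignments)
  out$.responsibility <- x$responsibilities[cbind(seq_len(x$n),
                                                  x$assignments)]
  out
}

#' @rdname tidy.lp_gmm
#' @param vars Length-2 character vector of feature columns to plot.
#' @export
autoplot.lp_gmm <- function(object, vars = NULL, ...) {
  vars <- vars %||% object$features[seq_len(min(2L, length(object$features)))]
  df <- augment(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[vars[1]]],
                                   y = .data[[vars[2]]],
                                   colour = .data$.cluster)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Transfer a baseline clustering onto another response
#'
#' Keeps the cluster labels of a baseline GMM fit and recomputes
#' per-cluster summaries and covariate dependencies on a different
#' response measured on the same rows, so intercluster behaviour of two
#' responses can be compared under one clustering configuration.
#'
#' @param baseline An `lp_gmm` fit.
#' @param data The same table (row-identical) the baseline was fitted on.
#' @param response Column name of the other response.
#' @param alpha Significance level forwarded to
#'   [within_cluster_dependence()].
#' @return A list of class `lp_gmm_transfer`: `assignments` (length
#'   `nrow(data)`, `NA` for rows the baseline excluded), per-cluster
#'   `summaries`, and the `dependence` coefficient table.
#' @export
transfer_assignments <- function(baseline, data, response, alpha = 0.05) {
  stopifnot(inherits(baseline, "lp_gmm"))
  if (nrow(data) != baseline$n_input) {
    abort("`data` does not share row identity with the baseline fit.")
  }
  if (!response %in% names(data)) {
    abort(sprintf("response column '%s' not found", response))
  }
  assignments <- rep(NA_integer_, nrow(data))
  assignments[baseline$row_index] <- baseline$assignments
  y <- data[[response]]
  summaries <- tibble::tibble(cluster = seq_len(baseline$K)) |>
    dplyr::mutate(
      n = vapply(.data$cluster, function(k)
        sum(assignments == k & !is.na(y), na.rm = TRUE), integer(1)),
      mean = vapply(.data$cluster, function(k)
        mean(y[which(assignments == k)], na.rm = TRUE), numeric(1)),
      sd = vapply(.data$cluster, function(k)
        sd(y[which(assignments == k)], na.rm = TRUE), numeric(1)))
  dep <- within_cluster_dependence(data, assignments, response,
                                   baseline$covariates, alpha = alpha)
  structure(list(baseline_response = baseline$response, response = response,
                 K = baseline$K, assignments = assignments,
                 summaries = summaries, dependence = dep),
            class = "lp_gmm_transfer")
}

#' @export
print.lp_gmm_transfer <- function(x, ...) {
  cat("<lp_gmm_transfer> baseline '", x$baseline_response, "' -> '",
      x$response, "' (", x$K, " clusters)\n", sep = "")
  print(x$summaries)
  invisible(x)
}
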