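trace_cols <- function() {
  c(outer(c("ecs_trace_", "p700_trace_"), lp_phases(), paste0))
}

#' Write and read raw-measurement tables
#'
#' Raw measurements travel as CSV with one row per leaf; DIRK trace
#' list-columns are serialized as JSON objects (`{"time":[...],
#' "value":[...]}`) inside their cells so the file stays plain text.
#' `write_measurement_json()` writes one JSON file per leaf into a
#' directory instead.
#'
#' @param measurements Raw-measurement tibble (see [simulate_dataset()]).
#' @param path Output CSV file (or directory for the JSON writer).
#' @return `path`, invisibly; `read_measurements()` returns the tibble.
#' @export
write_measurements <- function(measurements, path) {
  out <- measurements
  for (col in intersect(trace_cols(), names(out))) {
    out[[col]] <- vapply(out[[col]], function(tr) {
      jsonlite::toJSON(list(time = tr$time, value = tr$value),
                       digits = NA, auto_unbox = FALSE)
    }, character(1))
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  for (col in intersect(trace_cols(), names(out))) {
    out[[col]] <- purrr::map(out[[col]], function(s) {
      x <- jsonlite::fromJSON(s)
      tibble::tibble(time = x$time, value = x$value)
    })
  }
  out
}

#' @rdname write_measurements
#' @export
write_measurement_json <- function(measurements, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(measurements))) {
    row <- as.list(measurements[i, ])
    for (col in intersect(trace_cols(), names(row))) {
      row[[col]] <- as.list(row[[col]][[1]])
    }
    jsonlite::write_json(row, file.path(path,
                                        paste0(measurements$leaf_id[i], ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a PhotosynQ-style export
#'
#' Reads a tabular CSV or JSON export, renames columns through the
#' configured column map, and detects whether raw DIRK traces are present
#' (raw mode: returns a raw-measurement table for [derive_parameters()])
#' or only device-computed parameters (pass-through mode: returns a
#' derived-record table, completing light-potential difference columns if
#' absent).
#'
#' @param path CSV or JSON file.
#' @param config A [pipeline_config()] (its `$input$column_map` maps
#'   internal names to export column names).
#' @return A tibble with attribute `"mode"` set to `"raw"` or
#'   `"derived"`.
#' @export
read_photosynq <- function(path, config = pipeline_config()) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_csv(path, show_col_types = FALSE)
  }
  map <- config$input$column_map
  for (internal in names(map)) {
    ext <- map[[internal]]
    if (ext %in% names(raw) && !identical(ext, internal)) {
      names(raw)[names(raw) == ext] <- internal
    }
  }
  required <- config$input$required_columns %||%
    c("leaf_id", "par_amb", "t_leaf")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    abort(paste0("export is missing required columns: ",
                 paste(miss, collapse = ", ")))
  }
  has_traces <- any(trace_cols() %in% names(raw))
  if (has_traces) {
    for (col in intersect(trace_cols(), names(raw))) {
      if (is.character(raw[[col]])) {
        raw[[col]] <- purrr::map(raw[[col]], function(s) {
          x <- jsonlite::fromJSON(s)
          tibble::tibble(time = x$time, value = x$value)
        })
      }
    }
    attr(raw, "mode") <- "raw"
  } else {
    raw <- add_differences(raw)
    attr(raw, "mode") <- "derived"
  }
  raw
}

#' Pipeline configuration
#'
#' Nested configuration for [run_pipeline()]; every stage reads only its
#' own section. Round-trips losslessly through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param ... Named sections overriding the defaults (merged recursively).
#' @return A list of class `lp_pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(simulate = list(n_leaves = 50))
#' cfg$simulate$n_leaves
pipeline_config <- function(...) {
  defaults <- list(
    input = list(path = NULL,
                 column_map = list(),
                 required_columns = c("leaf_id", "par_amb", "t_leaf")),
    simulate = list(enabled = TRUE, n_leaves = 500, seed = 1,
                    defect_frac = 0, flat_frac = 0),
    derive = list(lef_coeff = 0.42, npqt_const = 4.88, par_high = 2000,
                  r2_floor = 0.5),
    qc = list(blacklist = character(), rules = unclass(qc_rules()),
              mode = "exclude"),
    cluster = list(responses = list("lef_amb"),
                   covariates = c("sqrt_par", "t_leaf"),
                   K = 1:6, families = lp_gmm_families(), n_init = 3,
                   seed = 1, standardize = TRUE),
    mechanism = list(margin = 0,
                     gmm_inputs = c("ql_high_amb", "p700_high_amb",
                                    "t_leaf")),
    output_dir = "lightpotential-run"
  )
  merge_rec <- function(a, b) {
    for (nm in names(b)) {
      val <- if (is.list(a[[nm]]) && is.list(b[[nm]])) {
        merge_rec(a[[nm]], b[[nm]])
      } else b[[nm]]
      a[nm] <- list(val) # keeps explicit NULLs instead of deleting
    }
    a
  }
  cfg <- merge_rec(defaults, list(...))
  # canonical shapes so the config round-trips losslessly through YAML
  cfg$qc$blacklist <- as.character(unlist(cfg$qc$blacklist))
  cfg$cluster$responses <- as.list(unlist(cfg$cluster$responses))
  cfg$input$required_columns <- as.character(unlist(cfg$input$required_columns))
  structure(cfg, class = "lp_pipeline_config")
}

#' @rdname pipeline_config
#' @param config A pipeline config.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

write_gmm_json <- function(fit, path) {
  jsonlite::write_json(list(
    K = fit$K, family = fit$family, weights = fit$weights,
    means = fit$means, covariances = fit$covariances,
    features = fit$features, bic = fit$bic, bic_table = fit$bic_table,
    seed = fit$seed, n = fit$n, n_excluded = fit$n_excluded
  ), path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Run the full light-potential pipeline
#'
#' Executes simulate (optional) -> derive -> qc -> cluster (one GMM per
#' configured response) -> mechanism, writing all tables, fits, flags and
#' reports plus a run manifest (config hash, seed, row counts per stage)
#' under `config$output_dir`. A stage failure halts with the stage name;
#' artifacts written before the failure are preserved.
#'
#' @param config A [pipeline_config()].
#' @return The output directory, invisibly; the manifest as attribute
#'   `"manifest"`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "lp_pipeline_config"))
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = rlang::hash(unclass(config)),
                   seed = config$simulate$seed,
                   r_version = as.character(getRversion()),
                   stages = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  measurements <- stage("input", {
    if (isTRUE(config$simulate$enabled)) {
      sc <- do.call(sim_config, config$simulate[
        setdiff(names(config$simulate), "enabled")])
      sim <- simulate_dataset(sc)
      readr::write_csv(sim$truth, file.path(out_dir, "ground_truth.csv"))
      write_measurements(sim$measurements,
                         file.path(out_dir, "measurements.csv"))
      sim$measurements
    } else {
      read_photosynq(config$input$path, config)
    }
  })

  records <- stage("derive", {
    if (identical(attr(measurements, "mode"), "derived")) {
      measurements
    } else {
      do.call(derive_parameters, c(list(measurements), config$derive))
    }
  })
  readr::write_csv(records, file.path(out_dir, "records.csv"))

  flags <- stage("qc", {
    rules <- do.call(qc_rules, config$qc$rules)
    qc_flags(records, rules, config$qc$blacklist)
  })
  readr::write_csv(flags, file.path(out_dir, "qc_flags.csv"))
  analysis <- apply_qc(records, flags, mode = config$qc$mode %||% "exclude")
  n_excluded <- length(unique(flags$leaf_id[flags$severity == "exclude"]))
  manifest$stages$qc <- list(n_total = nrow(records), n_flags = nrow(flags),
                             n_excluded = n_excluded,
                             n_analysis = nrow(records) - n_excluded)

  fits <- stage("cluster", {
    out <- list()
    for (resp in config$cluster$responses) {
      fit <- fit_gmm(analysis, resp,
                     covariates = config$cluster$covariates,
                     K = config$cluster$K,
                     families = config$cluster$families,
                     n_init = config$cluster$n_init,
                     seed = config$cluster$seed,
                     standardize = config$cluster$standardize)
      write_gmm_json(fit, file.path(out_dir, paste0("gmm_", resp, ".json")))
      col <- paste0("cluster_", resp)
      analysis[[col]] <- NA_integer_
      analysis[[col]][fit$row_index] <- fit$assignments
      out[[resp]] <- fit
    }
    out
  })

  report <- stage("mechanism", {
    inputs <- config$mechanism$gmm_inputs
    mfit <- fit_gmm(analysis, inputs[1], covariates = inputs[-1],
                    K = config$cluster$K, families = config$cluster$families,
                    n_init = config$cluster$n_init,
                    seed = config$cluster$seed,
                    standardize = config$cluster$standardize)
    write_gmm_json(mfit, file.path(out_dir, "gmm_mechanism.json"))
    assignments <- rep(NA_integer_, nrow(analysis))
    assignments[mfit$row_index] <- mfit$assignments
    rep <- mechanism_report(analysis, assignments,
                            margin = config$mechanism$margin)
    readr::write_csv(rep$clusters, file.path(out_dir,
                                             "mechanism_clusters.csv"))
    jsonlite::write_json(rep$clusters, file.path(out_dir,
                                                 "mechanism_clusters.json"),
                         auto_unbox = TRUE, digits = NA)
    rep
  })
  readr::write_csv(report$points, file.path(out_dir, "analysis.csv"))

  manifest$stages$cluster <- list(
    responses = unlist(config$cluster$responses),
    K_selected = vapply(fits, function(f) f$K, integer(1)))
  manifest$stages$mechanism <- list(n_clusters = nrow(report$clusters))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  structure(invisible(out_dir), manifest = manifest)
}
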