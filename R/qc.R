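#' Declarative quality-control rules
#'
#' Default rule set encoding the theoretical ranges of the derived
#' parameters, applied to every protocol phase: `phi2` and `ql` in
#' \[0, 1\], `npqt` in \[-0.1, 15\], `ecst >= 0`, `gh_plus` in (0, 500\]
#' s-1, DIRK fit R-squared >= 0.5 (missing or low-information fits count
#' as violations), and `fm' > fs`. Rules are plain named lists so they
#' round-trip losslessly through YAML; each rule has a `type`
#' (`"range"`, `"dirk_r2"`, or `"fluor_order"`) plus type-specific fields.
#'
#' @param ... Named rules overriding or extending the defaults; set a rule
#'   to `NULL` to drop it.
#' @return A named list of rules (class `lp_qc_rules`).
#' @export
#' @examples
#' rules <- qc_rules(npqt_range = list(type = "range", param = "npqt",
#'                                     min = 0, max = 10))
#' names(rules)
qc_rules <- function(...) {
  defaults <- list(
    phi2_range = list(type = "range", param = "phi2", min = 0, max = 1),
    ql_range = list(type = "range", param = "ql", min = 0, max = 1),
    npqt_range = list(type = "range", param = "npqt", min = -0.1, max = 15),
    ecst_range = list(type = "range", param = "ecst", min = 0),
    gh_plus_range = list(type = "range", param = "gh_plus", min = 0,
                         max = 500, min_exclusive = TRUE),
    dirk_r2 = list(type = "dirk_r2", min = 0.5),
    fluor_order = list(type = "fluor_order")
  )
  rules <- modifyList(defaults, list(...))
  rules <- rules[!vapply(rules, is.null, logical(1))]
  structure(rules, class = "lp_qc_rules")
}

new_flag <- function(leaf_id, rule_id, reason, severity = "exclude") {
  tibble::tibble(leaf_id = leaf_id, rule_id = rule_id, reason = reason,
                 severity = severity)
}

empty_flags <- function() new_flag(character(), character(), character(),
                                   character())

#' Flag measurements from blacklisted devices
#'
#' @param records A derived-record tibble with `leaf_id` and `device_id`.
#' @param blacklist Character vector of device ids whose records are
#'   flagged for exclusion.
#' @return A flag tibble (`leaf_id`, `rule_id`, `reason`, `severity`).
#' @export
flag_device <- function(records, blacklist) {
  stopifnot("device_id" %in% names(records))
  hit <- records$device_id %in% blacklist
  new_flag(records$leaf_id[hit], "device_blacklist",
           paste0("device ", records$device_id[hit], " is blacklisted"))
}

apply_range_rule <- function(records, id, rule) {
  flags <- empty_flags()
  for (ph in lp_phases()) {
    col <- paste0(rule$param, "_", ph)
    if (!col %in% names(records)) next
    x <- records[[col]]
    lo_bad <- if (isTRUE(rule$min_exclusive)) x <= (rule$min %||% -Inf)
              else x < (rule$min %||% -Inf)
    hi_bad <- x > (rule$max %||% Inf)
    bad <- !is.na(x) & (lo_bad | hi_bad)
    if (any(bad)) {
      flags <- dplyr::bind_rows(flags, new_flag(
        records$leaf_id[bad], id,
        sprintf("%s = %.4g outside theoretical range", col, x[bad])))
    }
  }
  flags
}

#' Flag parameter values outside theoretical ranges
#'
#' Applies a declarative rule set (see [qc_rules()]) to a derived-record
#' table. Flags never mutate the data; flagged records stay in the table.
#'
#' @param records Derived-record tibble from [derive_parameters()].
#' @param rules A rule list from [qc_rules()] (or YAML-loaded equivalent).
#' @return A flag tibble (`leaf_id`, `rule_id`, `reason`, `severity`),
#'   zero rows if nothing violates a rule.
#' @export
flag_ranges <- function(records, rules = qc_rules()) {
  flags <- list()
  for (id in names(rules)) {
    rule <- rules[[id]]
    type <- rule$type %||% "range"
    if (type == "range") {
      flags[[id]] <- apply_range_rule(records, id, rule)
    } else if (type == "dirk_r2") {
      fl <- empty_flags()
      for (col in grep("^(ecs|p700)_r2_", names(records), value = TRUE)) {
        r2 <- records[[col]]
        bad <- is.na(r2) | r2 < (rule$min %||% 0.5)
        if (any(bad)) {
          fl <- dplyr::bind_rows(fl, new_flag(
            records$leaf_id[bad], id,
            sprintf("%s = %.3g below fit-quality floor", col, r2[bad])))
        }
      }
      flags[[id]] <- fl
    } else if (type == "fluor_order") {
      fl <- empty_flags()
      for (ph in lp_phases()) {
        fs <- records[[paste0("fs_", ph)]]
        fm <- records[[paste0("fm_prime_", ph)]]
        if (is.null(fs) || is.null(fm)) next
        bad <- !is.na(fs) & !is.na(fm) & fm <= fs
        if (any(bad)) {
          fl <- dplyr::bind_rows(fl, new_flag(
            records$leaf_id[bad], id,
            sprintf("fm_prime_%s <= fs_%s", ph, ph)))
        }
      }
      flags[[id]] <- fl
    } else {
      abort(sprintf("unknown QC rule type '%s' in rule '%s'", type, id))
    }
  }
  out <- dplyr::bind_rows(flags)
  if (nrow(out) == 0L) empty_flags() else dplyr::distinct(out)
}

#' Run the full QC pass
#'
#' Combines device-blacklist and theoretical-range flagging.
#'
#' @inheritParams flag_ranges
#' @inheritParams flag_device
#' @return A flag tibble.
#' @export
qc_flags <- function(records, rules = qc_rules(), blacklist = character()) {
  dplyr::distinct(dplyr::bind_rows(flag_device(records, blacklist),
                                   flag_ranges(records, rules)))
}

#' Apply QC flags to an analysis table
#'
#' In `"exclude"` mode, records carrying at least one exclude-severity
#' flag are dropped from the returned analysis view (the input table is
#' never modified; all original data remain available). In `"keep"` mode
#' all rows are returned with `qc_flagged` and `qc_rules` annotation
#' columns.
#'
#' @param records Derived-record tibble.
#' @param flags Flag tibble from [qc_flags()].
#' @param mode `"exclude"` or `"keep"`.
#' @return A tibble.
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_leaves = 4, seed = 2))
#' rec <- derive_parameters(sim$measurements)
#' apply_qc(rec, qc_flags(rec), mode = "keep")$qc_flagged
apply_qc <- function(records, flags, mode = c("exclude", "keep")) {
  mode <- match.arg(mode)
  excl_ids <- unique(flags$leaf_id[flags$severity == "exclude"])
  if (mode == "exclude") {
    return(records[!records$leaf_id %in% excl_ids, , drop = FALSE])
  }
  ann <- flags |>
    dplyr::group_by(.data$leaf_id) |>
    dplyr::summarise(qc_rules = paste(sort(unique(.data$rule_id)),
                                      collapse = ";"),
                     .groups = "drop")
  out <- dplyr::left_join(records, ann, by = "leaf_id")
  out$qc_flagged <- out$leaf_id %in% unique(flags$leaf_id)
  out
}
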