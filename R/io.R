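record_columns <- c("session_id", "participant_id", "chart_index",
                    "component_labels", "level", "is_target",
                    "response_yes", "outcome", "rt_seconds")

#' Write and read response records as CSV
#'
#' Long-format interchange with external presentation front-ends: one row
#' per cell with columns `session_id`, `participant_id`, `chart_index`,
#' `component_labels` (semicolon-joined 1-based indices), `level`,
#' `is_target`, `response_yes` (booleans serialized as 0/1), `outcome`
#' and an optional pass-through `rt_seconds`. Reading validates every row's
#' outcome against the signal-detection table and reports offending line
#' numbers; a header-only file yields an empty record set.
#'
#' @param records Response records (e.g. a [run_session()]'s `records`,
#'   or [classify_chart()] output). Missing id columns are filled with
#'   `NA`.
#' @param path File path.
#' @return `read_records` returns the validated records data frame with
#'   logical `is_target`/`response_yes`; `write_records` returns `path`
#'   invisibly.
#' @export
write_records <- function(records, path) {
  records <- as.data.frame(records)
  for (col in record_columns) {
    if (!col %in% names(records)) records[[col]] <- rep(NA, nrow(records))
  }
  out <- records[record_columns]
  out$is_target <- as.integer(out$is_target)
  out$response_yes <- as.integer(out$response_yes)
  # serialize levels at full precision so the round-trip is lossless
  out$level <- sprintf("%.17g", out$level)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(component_labels = "character"))
  missing <- setdiff(setdiff(record_columns, "rt_seconds"), names(df))
  if (length(missing)) {
    stop("records file lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    df$is_target <- logical(0)
    df$response_yes <- logical(0)
    return(df)
  }
  df$is_target <- as.logical(df$is_target)
  df$response_yes <- as.logical(df$response_yes)
  expected <- classify_outcome(df$is_target, df$response_yes)
  bad <- which(df$outcome != expected)
  if (length(bad)) {
    # +1 for the header line
    stop("outcome inconsistent with (is_target, response_yes) at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  df
}

config_keys <- c("components", "n_charts", "grid", "target_fraction",
                 "dprime_placement", "initial_levels", "yaw_range",
                 "level_cap", "dprime_max", "cell_size_deg", "gap_deg",
                 "seed")
observer_keys <- c("theta", "gamma", "false_alarm", "lapse", "rule",
                   "dprime_max")

#' Load a session configuration (and optional observer spec) from YAML
#'
#' The YAML mirrors [session_config()] field for field; every omitted
#' field takes its documented default, so an empty file yields the full
#' default configuration. Unknown keys are rejected with the offending
#' key's name, and field validation errors name the field. An optional
#' `observer` block (`theta` map keyed by component, `gamma`,
#' `false_alarm`, `lapse`, `rule`) is materialized as a
#' [simulated_observer()].
#'
#' @param path Path to a YAML file.
#' @return A list with `config` (a `session_config`) and `observer`
#'   (a `simulated_observer` or `NULL`).
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config file must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(raw), c(config_keys, "observer"))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  obs_raw <- raw$observer
  raw$observer <- NULL
  if (!is.null(raw$components)) {
    raw$components <- lapply(raw$components, as.integer)
  }
  if (!is.null(raw$target_fraction)) {
    raw$target_fraction <- as.numeric(raw$target_fraction)
  }
  config <- do.call(session_config, raw)

  observer <- NULL
  if (!is.null(obs_raw)) {
    unknown_o <- setdiff(names(obs_raw), observer_keys)
    if (length(unknown_o)) {
      stop("unknown observer field(s): ", paste(unknown_o, collapse = ", "),
           call. = FALSE)
    }
    theta <- unlist(obs_raw$theta)
    observer <- simulated_observer(
      theta = theta,
      gamma = obs_raw$gamma %||% 1,
      false_alarm = obs_raw$false_alarm %||% 0.05,
      lapse = obs_raw$lapse %||% 0,
      rule = obs_raw$rule %||% "euclidean",
      dprime_max = obs_raw$dprime_max %||% 5)
  }
  list(config = config, observer = observer)
}

#' Save a session configuration to YAML
#'
#' Writes all fields explicitly so the file round-trips through
#' [load_config()] to an equal configuration.
#'
#' @param config A [session_config()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "session_config"))
  out <- unclass(config)
  out$components <- lapply(out$components, as.integer)
  if (is.null(out$seed)) out$seed <- NULL
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write threshold fits as JSON
#'
#' Serializes a session's (or cohort's) estimate table as a JSON array of
#' objects with fields `component_labels`, `theta_hat`, `se`, `gamma_hat`,
#' `F_hat`, `converged`, `n_charts`.
#'
#' @param estimates The `estimates` data frame of a [run_session()] or
#'   [simulate_cohort()] result.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_fits <- function(estimates, path) {
  fits <- lapply(seq_len(nrow(estimates)), function(i) {
    row <- estimates[i, ]
    list(component_labels = row$component_labels,
         theta_hat = row$theta_hat, se = row$se_theta,
         gamma_hat = row$gamma_hat, F_hat = row$false_alarm_hat,
         converged = row$converged, n_charts = row$n_charts_used)
  })
  jsonlite::write_json(fits, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to regenerate a run's outputs bit-identically:
#' the configuration snapshot, the master seed (recorded before any draw),
#' the per-chart child seeds actually used, the package version, and an
#' inventory of output files with MD5 checksums and a timestamp.
#'
#' @param path Destination JSON path.
#' @param config The [session_config()] used.
#' @param seed The master seed.
#' @param files Character vector of output file paths to inventory.
#' @param child_seeds Optional data frame of seeds actually used (e.g. the
#'   `audit` table of a [run_session()]).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, files = character(),
                           child_seeds = NULL) {
  files <- files[file.exists(files)]
  manifest <- list(
    schema_version = 1L,
    package = "findface",
    package_version = as.character(utils::packageVersion("findface")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = unclass(config),
    child_seeds = child_seeds,
    files = lapply(files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)),
           bytes = file.size(f))
    }))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}
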