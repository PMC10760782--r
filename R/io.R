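# Result serialization ------------------------------------------------------

#' Write model results to CSV
#'
#' CSV exports (UTF-8, header row, '.' decimal) mirroring the case-study
#' reporting layout: trajectories as tidy per-cycle state masses, QALY and
#' cost breakdowns as category-by-strategy tables, resources per group, PSA
#' samples, tornado tables and CEAC curves.
#'
#' @param x The object to export.
#' @param path Output file.
#' @return `path`, invisibly.
#' @name tcc_export
NULL

#' @rdname tcc_export
#' @export
write_trajectory_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname tcc_export
#' @param conventional,dht Per-arm results ([accumulate_effects()],
#'   [accumulate_costs()] or [accumulate_resources()] pairs).
#' @export
write_qaly_csv <- function(conventional, dht, path) {
  rows <- c(total_qalys = "total_qalys", care_stage = "cs_component",
            shl_loss = "shl_loss", care_consequence_loss = "event_loss",
            discounted_lys = "discounted_lys", undiscounted_lys = "undiscounted_lys")
  df <- data.frame(outcome = names(rows),
                   conventional = unlist(conventional[rows]),
                   dht = unlist(dht[rows]))
  df$difference <- df$dht - df$conventional
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tcc_export
#' @export
write_cost_csv <- function(conventional, dht, path) {
  cats <- c(cost_categories(), "total")
  df <- data.frame(category = cats, conventional = as.numeric(conventional[cats]),
                   dht = as.numeric(dht[cats]))
  df$difference <- df$dht - df$conventional
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tcc_export
#' @export
write_resources_csv <- function(conventional, dht, path) {
  groups <- names(conventional$care_hours)
  df <- data.frame(
    group = c(groups, "total"),
    hours_conventional = c(conventional$care_hours, conventional$total_hours),
    hours_dht = c(dht$care_hours, dht$total_hours),
    kg_conventional = c(conventional$disposal_kg, conventional$total_kg),
    kg_dht = c(dht$disposal_kg, dht$total_kg))
  df$hours_difference <- df$hours_dht - df$hours_conventional
  df$kg_difference <- df$kg_dht - df$kg_conventional
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tcc_export
#' @export
write_psa_csv <- function(x, path) {
  write.csv(x$samples, path, row.names = FALSE)
  invisible(path)
}

#' @rdname tcc_export
#' @export
write_owsa_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname tcc_export
#' @export
write_ceac_csv <- function(x, path) {
  write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to regenerate an output bit-identically:
#' parameter-set fingerprints, seed, scenario options, package version,
#' currency metadata, and which economics fields came from a synthetic
#' placeholder fixture.
#'
#' @param path Output JSON file.
#' @param ps The parameter set used.
#' @param seed Seed used for stochastic steps (or `NA`).
#' @param options Named list of scenario options worth recording.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, ps, seed = NA_integer_, options = list()) {
  manifest <- list(
    package = "tccmodel",
    version = as.character(utils::packageVersion("tccmodel")),
    fingerprint = param_fingerprint(ps),
    seed = seed,
    currency = ps$meta$currency %||% NA,
    price_year = ps$meta$price_year %||% NA,
    economics = if (is.null(ps$economics)) "absent"
                else if (isTRUE(ps$economics$synthetic)) "synthetic placeholder"
                else "populated",
    options = options)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Load a run configuration file
#'
#' YAML configuration for [tcc_main()]: parameter/economics fixture paths,
#' scenario toggles, sensitivity-analysis settings and the output directory.
#' Referenced files must exist.
#'
#' @param path YAML file.
#' @return Named list with defaults filled in.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(economics = "none", out_dir = ".", n_iter = 5000, seed = 1,
                   lambda_max = 150000, lambda_step = 1000)
  cfg <- modifyList(defaults, cfg)
  for (f in c("params")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("config references missing file: ", cfg[[f]], call. = FALSE)
    }
  }
  if (!cfg$economics %in% c("none", "synthetic") && !file.exists(cfg$economics)) {
    stop("config references missing economics file: ", cfg$economics, call. = FALSE)
  }
  cfg
}
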