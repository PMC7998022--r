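# End-to-end pipelines: phantom or NIfTI input -> scaling -> delay map ->
# sorted carpet -> crop -> edge detection -> transit summary, with every
# artifact written to a run directory.

pipeline_defaults <- function() {
  list(
    modality = "rs",
    bold = NULL, mask = NULL, etco2 = NULL, tr = NULL,
    phantom = NULL,                    # a phantom_spec for synthetic runs
    quality_floor = 0.3,
    max_lag = 10, band_low_hz = 0.01, band_high_hz = 0.1,
    filter_order = 4, upsample_dt_s = 0.072,
    polarity = "rising", f_max = 0.1,
    sigma_time = 2, sigma_row = 5, min_separation = 5,
    contrast_floor = 0.2, rate_floor = NULL, window = NULL,
    top_fraction = 0.15,
    seed = 1L, write_png = TRUE
  )
}

#' Assemble a pipeline configuration
#'
#' Validates user settings against the known keys and fills defaults.
#' Either `phantom` (a [phantom_spec()]) or `bold` (+`mask`) must be
#' supplied; `etco2` is required for the `co2` modality when no phantom is
#' given.
#'
#' @param ... Named settings overriding the defaults; unknown names are an
#'   error.
#' @return A validated config list of class `run_config`.
#' @export
run_config <- function(...) {
  user <- list(...)
  defs <- pipeline_defaults()
  unknown <- setdiff(names(user), names(defs))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defs, user)
  if (!cfg$modality %in% c("rs", "dsc", "co2"))
    stop("modality must be rs, dsc or co2")
  if (is.null(cfg$phantom) && is.null(cfg$bold))
    stop("either `phantom` or `bold` must be supplied")
  structure(cfg, class = "run_config")
}

#' Run the full SHAG pipeline
#'
#' Executes every stage for one dataset and writes `delays.tsv`,
#' `carpet.tsv`, `carpet.png`, `edges.tsv`, `summary.json`,
#' `config_resolved.json` and a `MANIFEST` into `out_dir`. On a stage
#' failure, artifacts of completed stages are retained and the MANIFEST
#' names the failed stage.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the delay map, carpet, edge set and
#'   summary.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  log_path <- file.path(out_dir, "run.log")
  note <- function(...) {
    msg <- sprintf(...)
    cat(format(Sys.time(), "%H:%M:%S "), msg, "\n", file = log_path,
        append = TRUE, sep = "")
  }
  done <- function(stage) {
    manifest <<- c(manifest, paste("ok", stage))
    writeLines(manifest, file.path(out_dir, "MANIFEST"))
  }
  fail <- function(stage, e) {
    manifest <<- c(manifest, paste("FAILED", stage, conditionMessage(e)))
    writeLines(manifest, file.path(out_dir, "MANIFEST"))
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  }
  stage <- function(name, expr) {
    note("stage %s", name)
    r <- tryCatch(expr, error = function(e) fail(name, e))
    done(name)
    r
  }

  cfg_json <- config
  cfg_json$phantom <- if (!is.null(config$phantom)) unclass(config$phantom)
  jsonlite::write_json(cfg_json, file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       force = TRUE)

  etco2 <- NULL
  vm <- stage("input", {
    if (!is.null(config$phantom)) {
      ph <- make_phantom(config$phantom)
      if (config$modality == "co2") etco2 <<- phantom_etco2(config$phantom)
      ph$matrix
    } else {
      if (!file.exists(config$bold)) stop("missing BOLD file: ", config$bold)
      run <- load_bold(config$bold, mask_path = config$mask, tr = config$tr)
      if (config$modality == "co2") {
        if (is.null(config$etco2)) stop("co2 modality needs `etco2`")
        etco2 <<- load_regressor(config$etco2)
      }
      extract_matrix(run)
    }
  })
  scaled <- stage("scale", scale_demean(vm))
  dmap <- stage("delays", switch(config$modality,
    rs = rs_delays(scaled, max_lag = config$max_lag,
                   band = c(config$band_low_hz, config$band_high_hz),
                   upsample_dt = config$upsample_dt_s,
                   filter_order = config$filter_order,
                   quality_floor = config$quality_floor),
    dsc = dsc_ttp(scaled, quality_floor = max(config$quality_floor, 0.5)),
    co2 = co2_delays(scaled, etco2, max_lag = max(config$max_lag, 15),
                     filter_order = config$filter_order,
                     quality_floor = config$quality_floor)))
  write_delay_map(dmap, file.path(out_dir, "delays.tsv"))
  carpet <- stage("build", {
    cp <- build_shag(scaled, dmap)
    crop_shag(cp, quality_floor = config$quality_floor)
  })
  write_matrix(voxel_matrix(carpet$data, carpet$dt,
                            voxel_ids = carpet$order, scaled = TRUE),
               file.path(out_dir, "carpet.tsv"))
  edges <- stage("detect", detect_edges(
    carpet, polarity = config$polarity, f_max = config$f_max,
    window = config$window, sigma_time = config$sigma_time,
    sigma_row = config$sigma_row, min_separation = config$min_separation,
    contrast_floor = config$contrast_floor, rate_floor = config$rate_floor))
  write_edges(edges, file.path(out_dir, "edges.tsv"))
  if (isTRUE(config$write_png))
    stage("render", render_carpet(carpet, file.path(out_dir, "carpet.png"),
                                  edges = edges))
  summary <- stage("summarize", {
    s <- summarize_transits(edges)
    grp <- group_top_fraction(edges, global_signal(carpet),
                              fraction = config$top_fraction)
    list(n_edges = s$n_edges, mean_transit_s = s$mean_s,
         sd_transit_s = s$sd_s, negatives = s$negatives,
         n_removed = carpet$n_removed,
         frac_removed = carpet$n_removed /
           (carpet$n_removed + nrow(carpet$data)),
         n_top_fraction = sum(grp$group == "top_fraction"),
         n_remainder = sum(grp$group == "remainder"))
  })
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  note("pipeline complete")
  invisible(list(delay_map = dmap, carpet = carpet, edges = edges,
                 summary = summary))
}
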