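#' Default pipeline configuration
#'
#' The resolved parameter set for a full run, as a nested list mirroring the
#' JSON config file: input calibration, reference frame, segmentation,
#' spike-detection, correlation and network parameters. Spike and network
#' defaults are the validated settings (`l = 10`, `th_z = 5`,
#' `influence = 0.50`, `th_r = 0.100`; `min_corr = 0.25`,
#' `max_dist_um = 208`, `max_delay_s = 0.5`).
#'
#' @return A nested list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    input = list(frames = character(), fps = 1, um_per_px = 1),
    reference_frame = 1L,
    segmentation = list(sigma_n = 1, sigma_a = 2, sigma_b = 6, th = 0.1,
                        connectivity = 8L, min_size_px = 4L),
    spikes = list(l = 10L, influence = 0.50, th_z = 5, th_r = 0.100,
                  min_spikes = 0L),
    correlation = list(signal = "s", max_lag = 5L),
    network = list(min_corr = 0.25, max_dist_um = 208, max_delay_s = 0.5)
  ), class = "run_config")
}

modify_defaults <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      modify_defaults(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}

#' Read and validate a pipeline configuration file
#'
#' The config is JSON with the structure of [default_config()]; absent
#' entries take the defaults. Validation errors abort before any
#' computation.
#'
#' @param path JSON file.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_config(modify_defaults(unclass(default_config()), user))
}

validate_config <- function(cfg) {
  with(cfg$input, {
    if (fps <= 0) abort("Config error: input$fps must be > 0.")
    if (um_per_px <= 0) abort("Config error: input$um_per_px must be > 0.")
  })
  seg <- cfg$segmentation
  do.call(segmentation_params, seg)
  do.call(spike_params, cfg$spikes)
  do.call(network_params, cfg$network)
  if (!cfg$correlation$signal %in% c("b", "r", "s")) {
    abort("Config error: correlation$signal must be one of 'b', 'r', 's'.")
  }
  structure(cfg, class = "run_config")
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
  writeLines(msg, con)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Orchestrates load, segment, trace extraction, spike detection,
#' cross-correlation, network reconstruction and export. Every artifact is
#' written into `out_dir`: `rois.csv`, `mask.tiff`, `traces.csv`,
#' `rates.csv`, `spikes.csv`, `correlations.csv`, `edges.csv`,
#' `adjacency.csv`, the resolved `config.json` and a timestamped `run.log`.
#' Outputs are a pure function of the inputs and the resolved config; a
#' rerun produces byte-identical CSVs. A movie with no detectable cells
#' completes with a warning and empty downstream tables. Stage failures
#' abort with a stage-named diagnostic.
#'
#' @param config A `run_config` list, or the path of a JSON config file.
#' @param out_dir Output directory (created if needed).
#' @param stack Optionally, an already loaded [image_stack()]; otherwise the
#'   frames named in the config are loaded.
#' @return Invisibly, a list with the intermediate results (`rois`,
#'   `traces`, `rates`, `spikes`, `correlations`, `network`).
#' @export
run_pipeline <- function(config, out_dir, stack = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(unclass(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  t0 <- Sys.time()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  if (is.null(stack)) {
    stack <- stage("load", load_stack(config$input$frames,
                                      fps = config$input$fps,
                                      um_per_px = config$input$um_per_px))
  }
  log_line(logf, "load: %d frame(s) %dx%d px", n_frames(stack),
           dim(stack)[1], dim(stack)[2])

  seg <- do.call(segmentation_params, config$segmentation)
  rois <- stage("segment", detect_rois(stack, config$reference_frame, seg))
  log_line(logf, "segment: %d ROI(s)", nrow(rois))
  write_rois_csv(rois, file.path(out_dir, "rois.csv"))
  write_label_mask(rois, file.path(out_dir, "mask.tiff"))

  empty <- nrow(rois) == 0L
  results <- list(config = config, rois = rois, traces = NULL, rates = NULL,
                  spikes = NULL, correlations = NULL, network = NULL)
  if (empty) {
    warn("No ROIs detected; downstream tables are empty.")
    for (f in c("traces.csv", "rates.csv", "spikes.csv", "correlations.csv",
                "edges.csv", "adjacency.csv")) {
      readr::write_csv(tibble(), file.path(out_dir, f))
    }
    log_line(logf, "pipeline: finished empty in %.2f s",
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  } else {
    traces <- stage("traces", extract_traces(stack, rois))
    write_traces_csv(traces, file.path(out_dir, "traces.csv"))
    rates <- stage("rates", rate_of_change(traces))
    write_rates_csv(rates, file.path(out_dir, "rates.csv"))
    log_line(logf, "traces: %d ROI(s) x %d frame(s)", nrow(rois), n_frames(stack))

    sp <- do.call(spike_params, config$spikes)
    spikes <- stage("spikes", detect_spikes(rates, sp))
    spikes <- filter_active(spikes, sp$min_spikes)
    write_spikes_csv(spikes, file.path(out_dir, "spikes.csv"))
    log_line(logf, "spikes: %d spike(s) in %d active ROI(s)",
             sum(spikes$spike), length(unique(spikes$roi_id)))

    signal_tbl <- switch(config$correlation$signal,
                         b = traces, r = rates, s = spikes)
    np <- do.call(network_params, config$network)
    max_lag <- max(config$correlation$max_lag,
                   floor(np$max_delay_s * attr(stack, "fps")))
    corr <- NULL
    net <- NULL
    if (length(unique(signal_tbl$roi_id)) >= 2L) {
      corr <- stage("correlate",
                    correlation_table(signal_tbl, lags = -max_lag:max_lag))
      readr::write_csv(corr, file.path(out_dir, "correlations.csv"))
      net <- stage("network",
                   reconstruct_network(rois, signal_tbl,
                                       fps = attr(stack, "fps"),
                                       um_per_px = attr(stack, "um_per_px"),
                                       params = np))
      write_edges_csv(net$edges, file.path(out_dir, "edges.csv"))
      adj <- as.data.frame(adjacency(net))
      readr::write_csv(dplyr::bind_cols(tibble(roi_id = rownames(adjacency(net))), adj),
                       file.path(out_dir, "adjacency.csv"))
      log_line(logf, "network: %d edge(s)", nrow(net$edges))
    } else {
      warn("Fewer than two active ROIs; correlation and network skipped.")
      readr::write_csv(tibble(), file.path(out_dir, "correlations.csv"))
      readr::write_csv(tibble(), file.path(out_dir, "edges.csv"))
      readr::write_csv(tibble(), file.path(out_dir, "adjacency.csv"))
    }
    results$traces <- traces
    results$rates <- rates
    results$spikes <- spikes
    results$correlations <- corr
    results$network <- net
    log_line(logf, "pipeline: finished in %.2f s",
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(results)
}
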