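#' Pipeline configuration
#'
#' All thresholds and windows of the analysis with their standard
#' values. The configuration round-trips losslessly through YAML via
#' [write_config()] / [read_config()].
#'
#' @param ... overrides of the default fields.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    neuropil_coeff = 0.5,      # Fcorr = F - coeff * Fneu
    high_threshold = 0.05,     # active, high threshold (fraction dF/F0)
    high_responder = 0.15,     # "high responding" cut (fraction dF/F0)
    qc_peak = 0.10,            # ROI QC: at least one peak above this
    r2_threshold = 0.7,        # tuning-fit validity
    jaccard = 0.5,             # frame-similarity cut
    min_coactive = 3,          # frames entering the ensemble pipeline
    percentile = 95,           # surrogate cut
    n_shifts = 1000,           # surrogates per pair
    speed_threshold = 3,       # cm/s, active exploration
    stim_window = 3,           # s, multistim analysis window
    plasticity_window = 10,    # s, plasticity analysis window
    max_lag = 50,              # overlap lags (frames)
    seed = 1
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) do.call(pipeline_config, yaml::read_yaml(path))

#' Write a recording to a directory of delimited tables
#'
#' Emits `F.csv`, `Fneu.csv`, `deconv.csv` (neurons x frames, header
#' row of frame columns), `schedule.csv` and `meta.yaml` (frame rate).
#'
#' @param recording a `recording`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(recording, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wm <- function(m, name) {
    ## %.17g guarantees doubles survive the text round trip exactly
    df <- as.data.frame(matrix(sprintf("%.17g", m), nrow(m), ncol(m)))
    names(df) <- paste0("frame_", seq_len(ncol(m)))
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = FALSE)
  }
  wm(recording$F, "F.csv")
  wm(recording$Fneu, "Fneu.csv")
  wm(recording$deconv, "deconv.csv")
  utils::write.csv(as.data.frame(recording$schedule),
                   file.path(dir, "schedule.csv"), row.names = FALSE)
  yaml::write_yaml(list(frame_rate = recording$frame_rate),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a recording from a directory of delimited tables
#'
#' Counterpart of [write_recording()]; validates that the three
#' matrices share their shape, that all values are finite, and that
#' the schedule covers every frame.
#'
#' @param dir directory holding `F.csv`, `Fneu.csv`, `deconv.csv`,
#'   `schedule.csv`, `meta.yaml`.
#' @return a `recording`.
#' @export
read_recording <- function(dir) {
  rm_ <- function(name) {
    p <- file.path(dir, name)
    if (!file.exists(p)) stop(sprintf("missing dataset '%s' in %s", name, dir))
    as.matrix(utils::read.csv(p))
  }
  F <- rm_("F.csv"); Fneu <- rm_("Fneu.csv"); deconv <- rm_("deconv.csv")
  sch <- utils::read.csv(file.path(dir, "schedule.csv"),
                         stringsAsFactors = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  schedule <- new_schedule(sch$label, sch$epoch, sch$cycle, sch$image,
                           meta$frame_rate)
  dimnames(F) <- dimnames(Fneu) <- dimnames(deconv) <- NULL
  new_recording(F, Fneu, deconv, schedule, meta$frame_rate)
}

#' Run the full analysis pipeline on a recording
#'
#' Preprocesses the recording, classifies stimulus responses, builds
#' the functional-connectivity graph and ensemble set on the kept
#' neurons, and computes the population metrics for the session mode:
#' multistim sessions get per-stimulus activity classes, response
#' AUCs, population sparseness, natural-image selectivity and von
#' Mises tuning fits; plasticity sessions get the 10-s session summary
#' entering the post/pre ratios. When `out_dir` is given every table
#' is written as CSV together with the configuration used.
#'
#' @param recording a `recording`.
#' @param mode "multistim" or "plasticity".
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return a report list; see details in the package vignette.
#' @export
run_pipeline <- function(recording, mode = c("multistim", "plasticity"),
                         config = pipeline_config(), out_dir = NULL) {
  mode <- match.arg(mode)
  traces <- preprocess_recording(recording, mode,
                                 neuropil_coeff = config$neuropil_coeff)
  kept <- which(traces$kept)
  if (length(kept) < 2L) stop("preprocess: fewer than 2 neurons pass QC")
  binary_kept <- traces$binary[kept, , drop = FALSE]

  report <- list(mode = mode, config = config, n_neurons = nrow(traces$dff),
                 n_kept = length(kept), kept = kept)

  if (mode == "multistim") {
    stims <- setdiff(unique(traces$schedule$label), "gray")
    cls <- list(); auc <- list()
    for (s in stims) {
      ta <- trial_average(traces, s, window = config$stim_window)
      cl <- classify_active(ta, high_threshold = config$high_threshold)
      cls[[s]] <- cl
      auc[[s]] <- response_auc(ta)
    }
    active_mat <- vapply(stims, function(s)
      cls[[s]]$active_low & traces$kept, logical(nrow(traces$dff)))
    report$classification <- cls
    report$auc <- auc
    report$active_fraction <- active_fraction(active_mat, nrow(traces$dff))
    report$sparseness <- vapply(stims, function(s)
      population_sparseness(auc[[s]]), numeric(1))

    ## natural-image selectivity from trial-averaged deconvolved events
    ni <- intersect(c("ni_1", "ni_2"), stims)
    if (length(ni)) {
      ev_tr <- traces; ev_tr$dff <- traces$events
      report$selectivity <- lapply(ni, function(s) {
        ta <- trial_average(ev_tr, s, window = config$stim_window)
        apply(ta$avg[kept, , drop = FALSE], 1L, function(a)
          suppressWarnings(selectivity_index(a)))
      })
      names(report$selectivity) <- ni
    }

    ## orientation tuning on grating AUCs of kept neurons
    gr <- paste0("grating_", GRATING_ANGLES)
    if (all(gr %in% stims)) {
      amat <- do.call(cbind, auc[gr])
      report$tuning <- lapply(kept, function(i)
        fit_von_mises(amat[i, ], GRATING_ANGLES,
                      r2_threshold = config$r2_threshold))
      names(report$tuning) <- kept
    }
    graph_binary <- binary_kept   # entire imaging period
  } else {
    onset <- which(traces$schedule$label != "gray")[1L]
    nw <- epoch_frames(config$plasticity_window, traces$frame_rate)
    graph_binary <- binary_kept[, onset:(onset + nw - 1L), drop = FALSE]
  }

  report$graph <- build_graph(graph_binary, n_shifts = config$n_shifts,
                              percentile = config$percentile,
                              seed = config$seed)
  report$ensembles <- detect_ensembles(binary_kept,
                                       min_coactive = config$min_coactive,
                                       n_surrogates = config$n_shifts,
                                       percentile = config$percentile,
                                       seed = config$seed)

  if (mode == "plasticity")
    report$summary <- plasticity_session_summary(traces, report$graph,
                                                 window = config$plasticity_window,
                                                 max_lag = config$max_lag)
  report$traces <- traces

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

## write the machine-readable report tables
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_config(report$config, file.path(out_dir, "config.yaml"))
  g <- report$graph
  utils::write.csv(as.data.frame(g$edges), file.path(out_dir, "edges.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(neuron = seq_along(g$degree), degree = g$degree),
                   file.path(out_dir, "degree.csv"), row.names = FALSE)
  utils::write.csv(data.frame(neuron = seq_len(nrow(report$ensembles$membership)),
                              report$ensembles$membership),
                   file.path(out_dir, "membership.csv"), row.names = FALSE)
  summary_fields <- list(mode = report$mode, n_neurons = report$n_neurons,
                         n_kept = report$n_kept,
                         degree_skewness = g$skewness)
  if (!is.null(report$active_fraction))
    summary_fields$active_fraction <- report$active_fraction
  if (!is.null(report$sparseness))
    summary_fields$sparseness <- as.list(report$sparseness)
  if (!is.null(report$summary)) summary_fields$session <- report$summary
  yaml::write_yaml(summary_fields, file.path(out_dir, "summary.yaml"))
  invisible(out_dir)
}
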