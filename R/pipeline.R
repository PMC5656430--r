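#' Validate a pipeline configuration
#'
#' Checks parameter ranges and file references of a configuration (a nested
#' list, typically read from YAML with \code{\link{read_config}}). Each
#' violation names the offending field and the constraint; entries with
#' severity \code{"error"} make the configuration non-runnable, entries with
#' severity \code{"warning"} (e.g. an unusual frame rate for the behavior) do
#' not.
#'
#' @param config nested configuration list.
#' @return data frame with columns \code{field}, \code{constraint},
#'   \code{severity}; zero error rows iff the configuration is runnable.
#' @export
validate_config <- function(config) {
  v <- list()
  bad <- function(field, constraint, severity = "error") {
    v[[length(v) + 1L]] <<- data.frame(field = field, constraint = constraint,
                                       severity = severity,
                                       stringsAsFactors = FALSE)
  }
  num_in <- function(x, lo, hi, open = TRUE) {
    is.numeric(x) && length(x) == 1 &&
      (if (open) x > lo && x < hi else x >= lo && x <= hi)
  }
  behavior <- config$behavior %||% "swim"
  if (!behavior %in% c("swim", "crawl", "bend")) {
    bad("behavior", "one of swim, crawl, bend")
  }
  alpha <- config$coherence$alpha %||% 0.05
  if (!num_in(alpha, 0, 1)) bad("coherence.alpha", "alpha in (0,1)")
  k <- config$coherence$k %||% 5
  nw <- config$coherence$nw %||% 3
  if (k < 2) bad("coherence.k", "k >= 2")
  if (k >= 2 * nw) bad("coherence.k", "k < 2 * nw")
  tau <- config$traces$salpa_tau_s
  if (!is.null(tau) && !num_in(tau, 1, 15, open = FALSE)) {
    bad("traces.salpa_tau_s", "time constant in [1, 15] s")
  }
  thr <- config$discrim$threshold %||% 0.75
  if (!num_in(thr, 0, 1, open = FALSE) || thr <= 0) {
    bad("discrim.threshold", "threshold in (0, 1]")
  }
  ch <- config$clusters$cut_height %||% 0.7
  if (!num_in(ch, 0, 2, open = FALSE)) {
    bad("clusters.cut_height", "cut height in [0, 2]")
  }
  mcs <- config$clusters$min_cluster_size %||% 3
  if (mcs < 1) bad("clusters.min_cluster_size", ">= 1")
  fr <- config$synth$frame_rate_hz %||%
    (if (behavior == "crawl") 20 else 50)
  if (behavior == "crawl" && fr != 20) {
    bad("synth.frame_rate_hz", "crawling is conventionally imaged at 20 Hz",
        "warning")
  }
  if (behavior %in% c("swim", "bend") && fr != 50) {
    bad("synth.frame_rate_hz",
        "bend/swim are conventionally imaged at 50 Hz", "warning")
  }
  if (!is.null(config$paths)) {
    for (f in names(config$paths)) {
      p <- config$paths[[f]]
      if (!is.null(p) && !file.exists(p)) {
        bad(paste0("paths.", f), "file must exist")
      }
    }
  }
  if (length(v) == 0) {
    return(data.frame(field = character(0), constraint = character(0),
                      severity = character(0)))
  }
  do.call(rbind, v)
}

#' Read a YAML pipeline configuration
#' @param path YAML file.
#' @return nested list.
#' @export
read_config <- function(path) {
  yaml::read_yaml(path)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order for one behavior: synthesize (or
#' load) a dual-view recording, estimate and correct motion per view, extract
#' and condition traces, then analyze (coherence and involvement candidates
#' for rhythmic behaviors, stimulus discriminability for local bending,
#' clustering with DVI/CI always), register ROIs to the canonical map, and
#' write all tables beneath \code{config$out}. The same configuration and
#' seed reproduce the report exactly.
#'
#' @param config nested configuration list; see \code{\link{validate_config}}.
#'   Main fields: \code{behavior}, \code{seed}, \code{out}, and the
#'   \code{synth}, \code{motion}, \code{traces}, \code{coherence},
#'   \code{discrim}, \code{clusters} blocks.
#' @return A \code{run_report}: list of stage outputs and summary tables with
#'   provenance (config hash, seed, parameters).
#' @export
run_pipeline <- function(config) {
  viol <- validate_config(config)
  errs <- viol[viol$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop_input("invalid configuration: ",
               paste(sprintf("%s (%s)", errs$field, errs$constraint),
                     collapse = "; "))
  }
  for (i in which(viol$severity == "warning")) {
    warning(sprintf("%s: %s", viol$field[i], viol$constraint[i]))
  }
  behavior <- config$behavior %||% "swim"
  seed <- config$seed %||% 1L
  out_dir <- config$out
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  # --- synthesize or load ----------------------------------------------------
  sy <- config$synth %||% list()
  if (!is.null(config$paths$recording)) {
    rec <- read_recording(config$paths$recording)
    map <- NULL
    protocol <- rec$events
  } else {
    map <- generate_canonical_map(sy$n_per_surface %||% 30L, seed = seed)
    program <- activity_program(map, seed = seed + 1L)
    protocol <- if (behavior == "bend") {
      stimulus_protocol(sy$n_trials %||% 20L)
    } else NULL
    vsim <- simulate_voltages(map, program, behavior = behavior,
                              protocol = protocol,
                              duration_s = sy$duration_s,
                              rate_hz = sy$frame_rate_hz,
                              seed = seed + 2L)
    shape <- sy$frame_shape %||% c(64L, 256L)
    prm <- imaging_params(
      frame_shape = shape,
      frame_rate_hz = vsim$rate_hz,
      shot_noise_ppm = sy$shot_noise_ppm %||% 70,
      motion_amp_px = sy$motion_amp_px %||% 0.3,
      um_per_px = sy$um_per_px %||% fit_um_per_px(map, shape))
    rec <- render_recording(vsim, prm, seed = seed + 3L)
  }
  rois <- truth_rois(rec)

  # --- per view: motion correction + trace conditioning ----------------------
  axes <- config$motion$axes %||% c("x", "y")
  run_motion <- !isFALSE(config$motion$enabled %||% TRUE)
  traces <- list(); trajs <- list()
  for (v in names(rec$stacks)) {
    stack <- rec$stacks[[v]]
    if (run_motion) {
      tj <- estimate_trajectory(stack, axes = axes)
      stack <- correct_stack(stack, tj)
      trajs[[v]] <- tj
    }
    traces[[v]] <- condition_traces(
      stack, rois, view = v,
      frame_rate_hz = rec$params$frame_rate_hz,
      time_constant_s = config$traces$salpa_tau_s)
  }
  dff <- cbind(traces$ventral$values, traces$dorsal$values)
  all_ids <- c(traces$ventral$ids, traces$dorsal$ids)
  colnames(dff) <- all_ids
  both <- structure(list(values = dff, ids = all_ids, view = "both",
                         frame_rate_hz = rec$params$frame_rate_hz,
                         stage = "dff"), class = "trace_set")

  report <- list(config_hash = config_hash(config), seed = seed,
                 behavior = behavior, violations = viol,
                 n_cells = length(all_ids))

  # --- analysis --------------------------------------------------------------
  co <- config$coherence %||% list()
  if (behavior %in% c("swim", "crawl")) {
    ref_id <- co$reference %||% rec$truth$reference_id
    cm <- coherence_map(both, reference = ref_id,
                        band_hz = co$band_hz %||% c(0.05, 5),
                        nw = co$nw %||% 3, k = co$k %||% 5,
                        alpha = co$alpha %||% 0.05)
    report$coherence <- cm
    if (!is.null(out_dir)) write_coherence(cm, file.path(out_dir, "coherence.csv"))
  } else {
    wr <- window_responses(both, protocol)
    sc <- prediction_scores(wr, config$discrim$threshold %||% 0.75)
    report$scores <- sc
    if (!is.null(out_dir)) {
      utils::write.csv(as.data.frame(sc),
                       file.path(out_dir, "prediction_scores.csv"),
                       row.names = FALSE)
    }
  }
  cl <- config$clusters %||% list()
  if (!is.null(map)) {
    surfaces <- stats::setNames(map$surface, map$id)
    ci <- cluster_integration(both, surfaces,
                              linkage_method = cl$linkage %||% "average",
                              cut_height = cl$cut_height %||% 0.7,
                              min_cluster_size = cl$min_cluster_size %||% 3L)
    report$clusters <- ci$table
    report$integration_coefficient <- ci$ci
    if (!is.null(out_dir)) {
      utils::write.csv(ci$table, file.path(out_dir, "clusters.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        stats::setNames(list(ci$ci), behavior),
        file.path(out_dir, "integration.json"), auto_unbox = TRUE,
        digits = NA)
    }
  }
  if (!is.null(trajs$ventral) && !is.null(out_dir)) {
    for (v in names(trajs)) {
      write_trajectory(trajs[[v]],
                       file.path(out_dir, paste0("trajectory_", v, ".csv")))
    }
  }
  report$trajectories <- trajs
  if (!is.null(rec$truth)) report$truth <- rec$truth
  structure(report, class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> behavior=%s seed=%s cells=%d (config %s)\n",
              x$behavior, x$seed, x$n_cells, substr(x$config_hash, 1, 8)))
  if (!is.null(x$integration_coefficient)) {
    cat(sprintf("  integration coefficient: %.3f\n",
                x$integration_coefficient))
  }
  if (!is.null(x$coherence)) {
    cat(sprintf("  coherence: %d/%d cells above the null threshold\n",
                sum(x$coherence$involved), nrow(x$coherence)))
  }
  if (!is.null(x$scores)) {
    st <- x$scores[x$scores$phase == "stimulus", ]
    cat(sprintf("  encoders (stimulus phase): %d/%d cells\n",
                sum(st$encoder), nrow(st)))
  }
  invisible(x)
}
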