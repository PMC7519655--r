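#' Pipeline configuration
#'
#' Assembles the full configuration for [run_pipeline()]: which stages to
#' run, the simulated-culture description, and every stage parameter block.
#' All analysis defaults equal the standard parameters of the recording
#' system (see [detection_params()], [cleaning_params()],
#' [tracing_params()], [burst_params()], [ccg_params()]).
#'
#' @param out_dir output directory; intermediates and reports are
#'   persisted there.
#' @param seed RNG seed recorded in every output.
#' @param stages subset of `c("simulate", "sta", "trace", "network")`.
#' @param array list `n_rows, n_cols, pitch` (a desk-scale sub-array by
#'   default).
#' @param simulate list: `n_neurons`, `duration_s`, `rate_hz`,
#'   `burst_rate_hz`, `burst_duration_s`, `burst_gain`, `n_connections`,
#'   `connection_prob`, `connection_latency_ms` (range), `noise`.
#' @param detection,cleaning,tracing,burst,ccg stage parameter objects.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "sta", "trace", "network"),
                            array = list(n_rows = 32L, n_cols = 64L, pitch = 18),
                            simulate = list(),
                            detection = detection_params(),
                            cleaning = cleaning_params(),
                            tracing = tracing_params(),
                            burst = burst_params(),
                            ccg = ccg_params()) {
  sim_defaults <- list(n_neurons = 8L, duration_s = 60, rate_hz = 2.4,
                       burst_rate_hz = 0.15, burst_duration_s = 0.8,
                       burst_gain = 8, n_connections = 4L,
                       connection_prob = 0.3,
                       connection_latency_ms = c(1, 5), noise = TRUE)
  simulate <- utils::modifyList(sim_defaults, simulate)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 array = array, simulate = simulate, detection = detection,
                 cleaning = cleaning, tracing = tracing, burst = burst,
                 ccg = ccg),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; parameter
#' blocks (`detection`, `cleaning`, `tracing`, `burst`, `ccg`) take the
#' argument names of the corresponding `*_params()` constructor.
#'
#' @param path YAML file.
#' @param out_dir override for the output directory.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  as_num <- function(x) if (is.list(x)) unlist(x) else x
  args <- list(out_dir = out_dir %||% y$out_dir %||% ".")
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$stages)) args$stages <- unlist(y$stages)
  if (!is.null(y$array)) args$array <- y$array
  if (!is.null(y$simulate)) args$simulate <- lapply(y$simulate, as_num)
  for (blk in c("detection", "cleaning", "tracing", "burst", "ccg"))
    if (!is.null(y[[blk]]))
      args[[blk]] <- do.call(paste0(blk, "_params"), lapply(y[[blk]], as_num))
  do.call(pipeline_config, args)
}

# Recursively strip S3 classes so arbitrary parameter objects serialize.
strip_classes <- function(x) {
  if (is.data.frame(x)) as.data.frame(x)
  else if (is.list(x)) lapply(unclass(x), strip_classes)
  else x
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(strip_classes(config), f, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(f))
}

write_footprint_tables <- function(fps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list()
  for (u in names(fps)) {
    fp <- fps[[u]]
    tab <- fp$table
    tab$noise_std_uv <- footprint_noise_std(fp)
    utils::write.csv(tab, file.path(dir, paste0("unit_", u, ".csv")),
                     row.names = FALSE)
    meta[[u]] <- list(fs = fp$fs, n_triggers = fp$n_triggers,
                      template_ms = fp$template_ms, init_id = fp$init_id)
  }
  jsonlite::write_json(meta, file.path(dir, "footprints.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

read_footprint_tables <- function(dir) {
  mf <- file.path(dir, "footprints.json")
  if (!file.exists(mf)) stop("stage sta has not run: missing ", mf)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  fps <- lapply(names(meta), function(u) {
    tab <- utils::read.csv(file.path(dir, paste0("unit_", u, ".csv")))
    structure(list(unit_id = u, table = tab, waveforms = NULL,
                   fs = meta[[u]]$fs, template_ms = meta[[u]]$template_ms,
                   n_triggers = meta[[u]]$n_triggers,
                   init_id = meta[[u]]$init_id),
              class = "footprint")
  })
  names(fps) <- names(meta)
  fps
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order -- simulate (ground-truth
#' dual-mode recording), sta (per-unit electrical footprints by
#' spike-triggered averaging), trace (footprint cleaning, axonal segments,
#' per-neuron morphometrics), network (bursts, connectivity graph) --
#' persisting every intermediate as plain text under `out_dir`. Runs are
#' deterministic given `seed`; a stage run on its own loads the previous
#' stage's persisted output.
#'
#' @param config a [pipeline_config()].
#' @return a `session_report`: list with `neurons` (per-neuron metric
#'   table), `bursts`, `ibis_s`, `edges`, `degrees`, `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  rec_dir <- file.path(out, "recording")
  sim <- config$simulate
  rec <- NULL

  if ("simulate" %in% config$stages) {
    arr <- hex_array(config$array$n_rows, config$array$n_cols,
                     config$array$pitch %||% 18)
    bounds <- list(xlim = range(arr$x), ylim = range(arr$y))
    max_len <- min(600, diff(bounds$xlim) * 0.6)
    neurons <- lapply(seq_len(sim$n_neurons), function(k)
      generate_arbor(bounds, neuron_id = k,
                     branch_length_um = c(min(300, 0.7 * max_len), max_len)))
    conns <- NULL
    if (sim$n_connections > 0 && sim$n_neurons >= 2) {
      pairs <- matrix(nrow = 0, ncol = 2)
      while (nrow(pairs) < sim$n_connections) {
        p <- sample.int(sim$n_neurons, 2L)
        if (!any(pairs[, 1] == p[1] & pairs[, 2] == p[2]))
          pairs <- rbind(pairs, p)
      }
      conns <- data.frame(pre = pairs[, 1], post = pairs[, 2],
                          latency_ms = stats::runif(nrow(pairs),
                            sim$connection_latency_ms[1],
                            sim$connection_latency_ms[2]),
                          prob = sim$connection_prob)
    }
    spec <- network_spec(sim$n_neurons, sim$rate_hz, conns,
                         sim$burst_rate_hz, sim$burst_duration_s,
                         sim$burst_gain)
    trains <- generate_network_spikes(spec, sim$duration_s)
    rendered <- render_recording(neurons, trains, arr, sim$duration_s,
                                 noise = isTRUE(sim$noise))
    rec <- rendered$recording
    write_recording(rec, rec_dir)
    write_ground_truth(rendered$truth, rec_dir, conns)
  }

  fps <- NULL
  if ("sta" %in% config$stages) {
    if (is.null(rec)) rec <- read_recording(rec_dir)
    if (!length(rec$units)) stop("stage sta: recording has no units")
    fs <- rec$aps_params$sampling_rate
    fps <- lapply(rec$units, function(spk) {
      tr <- align_triggers(spk + attr(biphasic_template(), "peak_s"),
                           fs, ncol(rec$aps), rec$t0)
      spike_triggered_average(rec$aps, fs, tr, rec$array,
                              config$detection$template_ms)
    })
    for (u in names(fps)) fps[[u]]$unit_id <- u
    write_footprint_tables(fps, file.path(out, "footprints"))
  }

  neurons_df <- NULL
  if ("trace" %in% config$stages) {
    if (is.null(fps)) fps <- read_footprint_tables(file.path(out, "footprints"))
    if (is.null(rec) && dir.exists(rec_dir)) rec <- read_recording(rec_dir)
    seg_rows <- list(); met_rows <- list()
    for (u in names(fps)) {
      fp <- fps[[u]]
      noise_std <- if (!is.null(fp$table$noise_std_uv)) fp$table$noise_std_uv
                   else footprint_noise_std(fp)
      cfp <- clean_footprint(fp, noise_std, config$cleaning)
      segs <- extract_all_segments(cfp, config$tracing)
      spk <- if (!is.null(rec)) rec$units[[u]]
      dur <- if (!is.null(rec)) recording_duration(rec)
      met_rows[[u]] <- morphometrics(segs, cfp, spk, dur)
      for (s in seq_along(segs)) {
        p <- segs[[s]]$path
        p$unit_id <- u; p$segment_id <- s
        seg_rows[[length(seg_rows) + 1L]] <- p
      }
    }
    neurons_df <- do.call(rbind, met_rows)
    rownames(neurons_df) <- NULL
    utils::write.csv(neurons_df, file.path(out, "neurons.csv"),
                     row.names = FALSE)
    segs_df <- if (length(seg_rows)) do.call(rbind, seg_rows)
    else data.frame(order = integer(0), id = integer(0), x = numeric(0),
                    y = numeric(0), latency_ms = numeric(0),
                    cumdist_um = numeric(0), unit_id = character(0),
                    segment_id = integer(0))
    utils::write.csv(segs_df, file.path(out, "segments.csv"),
                     row.names = FALSE)
  }

  bursts <- NULL; ibis <- NULL; net <- NULL
  if ("network" %in% config$stages) {
    if (is.null(rec)) rec <- read_recording(rec_dir)
    if (is.null(fps) && dir.exists(file.path(out, "footprints")))
      fps <- read_footprint_tables(file.path(out, "footprints"))
    dur <- recording_duration(rec)
    pr <- population_rate(rec$units, dur, config$burst)
    bd <- detect_bursts(pr, config$burst)
    bursts <- bd$bursts; ibis <- bd$ibis_s
    utils::write.csv(bursts, file.path(out, "bursts.csv"), row.names = FALSE)
    utils::write.csv(data.frame(ibi_s = ibis), file.path(out, "ibis.csv"),
                     row.names = FALSE)
    centers <- if (!is.null(fps)) {
      do.call(rbind, lapply(names(fps), function(u) {
        tab <- fps[[u]]$table
        i <- which.max(tab$amplitude_uv)
        data.frame(unit = u, x = tab$x[i], y = tab$y[i])
      }))
    } else data.frame(unit = names(rec$units), x = 0, y = 0)
    net <- build_graph(rec$units, centers, config$ccg)
    utils::write.csv(net$edges, file.path(out, "edges.csv"), row.names = FALSE)
    utils::write.csv(net$degrees, file.path(out, "degrees.csv"),
                     row.names = FALSE)
  }

  report <- structure(list(
    neurons = neurons_df, bursts = bursts, ibis_s = ibis,
    edges = if (!is.null(net)) net$edges,
    degrees = if (!is.null(net)) net$degrees,
    provenance = list(seed = config$seed, stages = config$stages,
                      config_md5 = config_hash(config),
                      package_version = as.character(
                        utils::packageVersion("hdmea")))),
    class = "session_report")
  jsonlite::write_json(strip_classes(report),
                       file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  report
}

report_metrics <- function(report) {
  out <- list()
  if (!is.null(report$neurons))
    for (m in c("n_segments", "longest_um", "total_um", "velocity_mms",
                "max_amp_uv", "rate_hz"))
      out[[m]] <- report$neurons[[m]]
  if (!is.null(report$bursts) && nrow(report$bursts))
    out$burst_duration_s <- report$bursts$duration_s
  if (!is.null(report$ibis_s)) out$ibi_s <- report$ibis_s
  if (!is.null(report$degrees)) out$degree <- report$degrees$degree
  if (!is.null(report$edges) && nrow(report$edges)) {
    out$connection_distance_um <- report$edges$distance_um
    out$connection_latency_ms <- report$edges$latency_ms
  }
  out
}

#' Compare feature distributions across sessions
#'
#' Longitudinal summary of the per-neuron and network metrics of several
#' session reports (for example the same culture at different days in
#' vitro): per metric and session the median, quartiles, and n. Sessions
#' must expose the same metric schema.
#'
#' @param reports named list of `session_report`s (names label sessions).
#' @return data.frame `metric, session, n, q25, median, q75`.
#' @export
compare_sessions <- function(reports) {
  if (is.null(names(reports)))
    names(reports) <- paste0("session_", seq_along(reports))
  mets <- lapply(reports, report_metrics)
  schemas <- lapply(mets, names)
  ref <- schemas[[1L]]
  for (k in seq_along(schemas))
    if (!identical(sort(schemas[[k]]), sort(ref)))
      stop("mismatched metric schemas: session '", names(reports)[k],
           "' differs in: ",
           paste(union(setdiff(ref, schemas[[k]]),
                       setdiff(schemas[[k]], ref)), collapse = ", "))
  rows <- list()
  for (s in names(mets)) for (m in ref) {
    v <- mets[[s]][[m]]
    v <- v[is.finite(v)]
    q <- if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    else rep(NA_real_, 3L)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = m, session = s, n = length(v),
      q25 = q[1L], median = q[2L], q75 = q[3L])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
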