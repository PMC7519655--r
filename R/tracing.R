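#' Footprint cleaning parameters
#'
#' Electrodes recording mostly noise are removed from a footprint before
#' tracing with two rules: the negative-peak amplitude must exceed
#' `amp_k` times the per-electrode noise sd of the averaged footprint, and
#' the peak-time dispersion must be below `jitter_max_ms`.
#'
#' @param amp_k amplitude threshold in noise-sd multiples (default 5.5).
#' @param jitter_max_ms maximum peak-time standard deviation, ms (default 0.7).
#' @export
cleaning_params <- function(amp_k = 5.5, jitter_max_ms = 0.7) {
  if (amp_k <= 0 || jitter_max_ms <= 0)
    stop("invalid parameter: amp_k and jitter_max_ms must be > 0")
  structure(list(amp_k = amp_k, jitter_max_ms = jitter_max_ms),
            class = "cleaning_params")
}

#' Tracing parameters
#'
#' @param radius_um search radius per frame step, um (default 80).
#' @param max_gap_frames maximum gap expansion R: if no electrode peaks in
#'   the preceding frame, frames N-2 .. N-R are searched with the radius
#'   widened to r x `radius_um` (default R = 5).
#' @param stop_frames stop the walk this many frames before the initiation
#'   frame, so the widely visible initiation-site signal is excluded
#'   (default 5).
#' @param min_electrodes discard segments with fewer electrodes (default 5,
#'   the minimum for a meaningful velocity fit).
#' @param corridor_um after a segment is accepted, electrodes within this
#'   lateral distance of its path are marked assigned too: they record the
#'   same branch (amplitude has decayed ~7x at 60 um) and would otherwise
#'   be re-traced as a duplicate parallel segment.
#' @export
tracing_params <- function(radius_um = 80, max_gap_frames = 5L,
                           stop_frames = 5L, min_electrodes = 5L,
                           corridor_um = 60) {
  if (radius_um <= 0) stop("invalid parameter: radius_um must be > 0")
  if (max_gap_frames < 1) stop("invalid parameter: max_gap_frames must be >= 1")
  structure(list(radius_um = radius_um,
                 max_gap_frames = as.integer(max_gap_frames),
                 stop_frames = as.integer(stop_frames),
                 min_electrodes = as.integer(min_electrodes),
                 corridor_um = corridor_um),
            class = "tracing_params")
}

#' Per-electrode noise sd of an averaged footprint
#'
#' Robust (median-absolute-deviation) estimate from the outer 15% of each
#' electrode's waveform window, which is baseline for templates centred on
#' the trigger. Averaging N windows reduces the raw noise by 1/sqrt(N), so
#' this is the right scale for the amplitude-cleaning rule.
#'
#' @param fp a `footprint`.
#' @param edge_frac fraction of the window on each side treated as baseline.
#' @return numeric vector, one sd per electrode (uV).
#' @export
footprint_noise_std <- function(fp, edge_frac = 0.15) {
  L <- ncol(fp$waveforms)
  k <- max(2L, as.integer(round(edge_frac * L)))
  idx <- c(seq_len(k), (L - k + 1L):L)
  apply(fp$waveforms[, idx, drop = FALSE], 1L, stats::mad)
}

#' Clean a footprint
#'
#' Keeps electrodes with `amplitude > amp_k * noise_std` AND
#' `jitter < jitter_max_ms` (electrodes with no jitter estimate pass the
#' jitter rule). Removing every electrode yields an empty footprint, not an
#' error. The initiation site and latencies are re-referenced on the kept
#' electrodes.
#'
#' @param fp a `footprint`.
#' @param noise_std per-electrode noise sd of the averaged footprint
#'   (scalar or vector); estimated with [footprint_noise_std()] if `NULL`.
#' @param params [cleaning_params()].
#' @return the cleaned `footprint`.
#' @export
clean_footprint <- function(fp, noise_std = NULL, params = cleaning_params()) {
  if (is.null(noise_std)) noise_std <- footprint_noise_std(fp)
  noise_std <- rep_len(noise_std, nrow(fp$table))
  keep <- fp$table$amplitude_uv > params$amp_k * noise_std &
    (is.na(fp$table$jitter_ms) | fp$table$jitter_ms < params$jitter_max_ms)
  fp$table <- fp$table[keep, , drop = FALSE]
  fp$waveforms <- fp$waveforms[keep, , drop = FALSE]
  rownames(fp$table) <- NULL
  if (nrow(fp$table)) {
    init <- which.max(fp$table$amplitude_uv)
    fp$init_id <- fp$table$id[init]
    shift <- fp$table$latency_ms[init]
    fp$table$latency_ms <- fp$table$latency_ms - shift
    if (!is.null(fp$table$latency_interp_ms))
      fp$table$latency_interp_ms <- fp$table$latency_interp_ms -
        fp$table$latency_interp_ms[init]
  } else fp$init_id <- NA_integer_
  fp
}

#' Initiation-site electrode of a footprint
#'
#' The electrode with the maximum negative-peak amplitude (the distal axon
#' initial segment produces the largest extracellular signal); ties break
#' toward the smaller electrode id. Its peak defines latency zero.
#'
#' @param fp a `footprint`.
#' @return electrode id.
#' @export
initiation_site <- function(fp) {
  if (!nrow(fp$table)) stop("empty footprint")
  fp$table$id[which.max(fp$table$amplitude_uv)]
}

#' Terminal candidates for segment extraction
#'
#' Unassigned electrodes that are local maxima of the delay map within
#' `radius_um` (no other cleaned electrode in the neighbourhood peaks
#' later), ordered by decreasing delay (ties by ascending id). Tracing a
#' segment from each candidate backward in time recovers one axonal branch
#' per candidate.
#'
#' An axon is seen by a corridor of electrodes several pitches wide, so
#' the flank electrodes of an already-traced segment would re-qualify as
#' terminals and duplicate the branch; a candidate is therefore also
#' rejected when an assigned electrode with equal or later delay lies
#' within the search radius.
#'
#' @param fp a cleaned `footprint`.
#' @param assigned electrode ids already assigned to a segment.
#' @param params [tracing_params()].
#' @return integer vector of electrode ids.
#' @export
terminal_candidates <- function(fp, assigned = integer(0),
                                params = tracing_params()) {
  tab <- fp$table
  if (!nrow(tab)) return(integer(0))
  free <- !(tab$id %in% assigned)
  if (!any(free)) return(integer(0))
  taken <- tab$id %in% assigned
  r2 <- (params$radius_um + 1e-6)^2
  is_max <- logical(nrow(tab))
  for (i in which(free)) {
    d2 <- (tab$x - tab$x[i])^2 + (tab$y - tab$y[i])^2
    nb <- d2 <= r2
    is_max[i] <- all(tab$latency_ms[nb] <= tab$latency_ms[i]) &&
      !any(taken[nb] & tab$latency_ms[nb] >= tab$latency_ms[i])
  }
  cand <- tab[is_max & free, ]
  cand$id[order(-cand$latency_ms, cand$id)]
}

#' Trace one axonal segment backward in time
#'
#' From the terminal electrode (latest peak frame N) the tracker walks
#' backward: among cleaned, unassigned electrodes peaking in frame N-1
#' within `radius_um` of the current electrode, the one with the largest
#' amplitude is chosen (ties by ascending id). If no electrode peaks in
#' the preceding frame (weak axonal signals cause gaps), the search widens
#' to frame N-r and radius r x `radius_um` for r = 2..`max_gap_frames`.
#' The walk stops when the next step would land within `stop_frames` of
#' the initiation frame, or when no candidate remains. The path is
#' returned in initiation-to-terminal order with summed inter-electrode
#' distances and a distance-vs-latency velocity fit.
#'
#' @param fp a cleaned `footprint`.
#' @param start terminal electrode id (must be in the cleaned footprint).
#' @param params [tracing_params()].
#' @param assigned electrode ids excluded from the walk.
#' @return object of class `axonal_segment`: list with `path` (data.frame
#'   `order, id, x, y, latency_ms, cumdist_um`), `length_um`,
#'   `velocity_mms`, `r_squared`, `degenerate`.
#' @export
trace_segment <- function(fp, start, params = tracing_params(),
                          assigned = integer(0)) {
  tab <- fp$table
  i_start <- match(as.integer(start), tab$id)
  if (is.na(i_start)) stop("start electrode not in cleaned footprint")
  init_frame <- tab$peak_frame[match(fp$init_id, tab$id)]
  frames <- tab$peak_frame
  avail <- !(tab$id %in% assigned)
  path <- i_start
  avail[i_start] <- FALSE
  cur <- i_start
  degenerate <- frames[i_start] < init_frame + params$stop_frames
  if (!degenerate) repeat {
    found <- FALSE
    for (r in seq_len(params$max_gap_frames)) {
      target <- frames[cur] - r
      if (target < init_frame + params$stop_frames) break
      r2 <- (r * params$radius_um + 1e-6)^2
      d2 <- (tab$x - tab$x[cur])^2 + (tab$y - tab$y[cur])^2
      cand <- which(avail & frames == target & d2 <= r2)
      if (length(cand)) {
        # largest amplitude, ties toward the smaller id (table is id-sorted)
        nxt <- cand[which.max(tab$amplitude_uv[cand])]
        path <- c(path, nxt)
        avail[nxt] <- FALSE
        cur <- nxt
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  path <- rev(path)                       # initiation-proximal -> terminal
  px <- tab$x[path]; py <- tab$y[path]
  step <- c(0, sqrt(diff(px)^2 + diff(py)^2))
  seg <- data.frame(order = seq_along(path), id = tab$id[path],
                    x = px, y = py,
                    latency_ms = tab$latency_ms[path],
                    cumdist_um = cumsum(step))
  if (!is.null(tab$latency_interp_ms))
    seg$latency_interp_ms <- tab$latency_interp_ms[path]
  out <- structure(list(path = seg, length_um = sum(step),
                        velocity_mms = NA_real_, r_squared = NA_real_,
                        degenerate = degenerate || length(path) == 1L),
                   class = "axonal_segment")
  fit <- fit_velocity(out)
  out$velocity_mms <- fit[["velocity_mms"]]
  out$r_squared <- fit[["r_squared"]]
  out
}

#' Conduction velocity of a segment
#'
#' Ordinary least-squares fit of cumulative path distance (um) against peak
#' latency (ms); the slope in um/ms equals the velocity in mm/s. Requires
#' at least 3 electrodes and non-zero latency spread, otherwise the
#' velocity is flagged undefined (`NA`). With `interp = TRUE` the fit uses
#' the sub-sample (parabola-refined) peak latencies when the footprint
#' carries them; the tracker itself always walks whole frames.
#'
#' @param seg an `axonal_segment`.
#' @param interp use interpolated peak latencies for the fit.
#' @return named numeric vector `velocity_mms`, `r_squared`.
#' @export
fit_velocity <- function(seg, interp = FALSE) {
  p <- seg$path
  lat <- if (interp && !is.null(p$latency_interp_ms)) p$latency_interp_ms
         else p$latency_ms
  if (nrow(p) < 3L || stats::sd(lat) == 0)
    return(c(velocity_mms = NA_real_, r_squared = NA_real_))
  fit <- stats::lm.fit(cbind(1, lat), p$cumdist_um)
  tss <- sum((p$cumdist_um - mean(p$cumdist_um))^2)
  c(velocity_mms = unname(fit$coefficients[2L]),
    r_squared = if (tss > 0) 1 - sum(fit$residuals^2) / tss else NA_real_)
}

#' Extract all axonal segments of a footprint
#'
#' Repeats [terminal_candidates()] -> [trace_segment()], marking traced
#' electrodes -- and the corridor of electrodes within `corridor_um` of
#' the path, which record the same branch -- as assigned so later traces
#' cannot duplicate them (shared proximal trunks are attributed to the
#' first-traced branch), until no candidate remains. Segments shorter than
#' `min_electrodes` are discarded (their terminal is retired, their
#' electrodes stay available).
#'
#' @param fp a cleaned `footprint`.
#' @param params [tracing_params()].
#' @return list of `axonal_segment`s.
#' @export
extract_all_segments <- function(fp, params = tracing_params()) {
  if (!nrow(fp$table)) return(list())
  assigned <- integer(0)
  retired <- integer(0)
  segs <- list()
  repeat {
    cand <- terminal_candidates(fp, c(assigned, retired), params)
    if (!length(cand)) break
    seg <- trace_segment(fp, cand[1L], params, assigned)
    if (!seg$degenerate && nrow(seg$path) >= params$min_electrodes) {
      segs[[length(segs) + 1L]] <- seg
      near <- rep(FALSE, nrow(fp$table))
      for (k in seq_len(nrow(seg$path)))
        near <- near | ((fp$table$x - seg$path$x[k])^2 +
                        (fp$table$y - seg$path$y[k])^2 <=
                        (params$corridor_um + 1e-6)^2)
      assigned <- unique(c(assigned, seg$path$id, fp$table$id[near]))
    } else retired <- c(retired, cand[1L])
  }
  segs
}

#' Per-neuron morphometrics
#'
#' Summary of one neuron's traced arbor and activity: segment count,
#' longest segment (um), total extension (sum of all assigned segment
#' lengths, um), mean conduction velocity over valid fits (mm/s), maximum
#' footprint amplitude (uV), and firing rate (Hz).
#'
#' @param segments list of `axonal_segment`s.
#' @param fp the neuron's `footprint` (may be the cleaned one).
#' @param spike_times spike train, seconds (optional).
#' @param duration_s recording duration for the firing rate (optional).
#' @return one-row data.frame `n_segments, longest_um, total_um,
#'   velocity_mms, r_squared, max_amp_uv, rate_hz`.
#' @export
morphometrics <- function(segments, fp, spike_times = NULL, duration_s = NULL) {
  lens <- vapply(segments, function(s) s$length_um, numeric(1))
  vels <- vapply(segments, function(s) s$velocity_mms, numeric(1))
  r2s <- vapply(segments, function(s) s$r_squared, numeric(1))
  data.frame(
    unit_id = if (is.null(fp$unit_id)) NA else fp$unit_id,
    n_segments = length(segments),
    longest_um = if (length(lens)) max(lens) else 0,
    total_um = sum(lens),
    velocity_mms = if (any(!is.na(vels))) mean(vels, na.rm = TRUE) else NA_real_,
    r_squared = if (any(!is.na(r2s))) mean(r2s, na.rm = TRUE) else NA_real_,
    max_amp_uv = if (nrow(fp$table)) max(fp$table$amplitude_uv) else NA_real_,
    rate_hz = if (!is.null(spike_times) && !is.null(duration_s))
      length(spike_times) / duration_s else NA_real_)
}
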