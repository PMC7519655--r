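#' Recording-mode parameters
#'
#' The dual-mode chip samples two streams simultaneously: a full-frame
#' ("APS") stream covering every electrode at 11.6 kHz with 10.4 uV rms
#' noise, and a low-noise switch-matrix ("SM") stream of up to 246 selected
#' electrodes at 24.4 kHz with 3.0 uV rms noise. Noise figures are rms in
#' the action-potential band (0.3-5 kHz).
#'
#' @param mode `"full_frame"` or `"high_snr"`.
#' @param sampling_rate Hz; defaults 11600 (full frame) / 24400 (high SNR).
#' @param noise_rms uV rms in the 0.3-5 kHz band; defaults 10.4 / 3.0.
#' @param n_channels channel count; the high-SNR stream supports at most 246.
#' @return list of class `mode_params`.
#' @export
mode_params <- function(mode = c("full_frame", "high_snr"),
                        sampling_rate = NULL, noise_rms = NULL,
                        n_channels = NULL) {
  mode <- match.arg(mode)
  if (is.null(sampling_rate))
    sampling_rate <- if (mode == "full_frame") 11600 else 24400
  if (is.null(noise_rms))
    noise_rms <- if (mode == "full_frame") 10.4 else 3.0
  sampling_rate <- as.numeric(sampling_rate)
  noise_rms <- as.numeric(noise_rms)
  if (sampling_rate <= 0) stop("invalid parameter: sampling_rate must be > 0")
  if (noise_rms < 0) stop("invalid parameter: noise_rms must be >= 0")
  if (mode == "high_snr" && !is.null(n_channels) && n_channels > 246)
    stop("invalid parameter: high_snr supports at most 246 channels")
  structure(list(mode = mode, sampling_rate = sampling_rate,
                 noise_rms = noise_rms, n_channels = n_channels),
            class = "mode_params")
}

#' Dual-mode recording container (in memory)
#'
#' Holds the two simultaneously sampled streams in uV, sharing one clock
#' origin `t0`. The full-frame matrix has one row per array electrode (in
#' ascending-id order); the high-SNR matrix has one row per selected
#' electrode in the order of `sm_electrodes`.
#'
#' @param aps electrodes x frames matrix, uV.
#' @param aps_params `mode_params` for the full-frame stream.
#' @param array the `electrode_array`.
#' @param sm optional selected-electrodes x samples matrix, uV.
#' @param sm_params `mode_params` for the high-SNR stream.
#' @param sm_electrodes electrode ids of the high-SNR rows (subset of array).
#' @param t0 shared clock origin, seconds.
#' @param units optional named list of spike-time vectors (seconds) per unit.
#' @return list of class `dual_mode_recording`.
#' @export
dual_mode_recording <- function(aps, aps_params, array, sm = NULL,
                                sm_params = NULL, sm_electrodes = integer(0),
                                t0 = 0, units = NULL) {
  aps <- as.matrix(aps)
  if (nrow(aps) != n_electrodes(array))
    stop("invalid parameter: aps rows must match array electrode count")
  sm_electrodes <- as.integer(sm_electrodes)
  if (length(sm_electrodes)) {
    if (!all(sm_electrodes %in% array$ids))
      stop("invalid parameter: sm_electrodes must be a subset of array electrodes")
    if (is.null(sm) || nrow(as.matrix(sm)) != length(sm_electrodes))
      stop("invalid parameter: sm rows must match sm_electrodes")
    sm <- as.matrix(sm)
    if (is.null(sm_params)) sm_params <- mode_params("high_snr")
  }
  structure(list(aps = aps, aps_params = aps_params, sm = sm,
                 sm_params = sm_params, sm_electrodes = sm_electrodes,
                 array = array, t0 = t0, units = units),
            class = "dual_mode_recording")
}

#' @export
print.dual_mode_recording <- function(x, ...) {
  cat(sprintf("<dual_mode_recording> %d electrodes, %.3f s full-frame @ %g Hz",
              nrow(x$aps), ncol(x$aps) / x$aps_params$sampling_rate,
              x$aps_params$sampling_rate))
  if (length(x$sm_electrodes))
    cat(sprintf("; %d high-SNR channels @ %g Hz", length(x$sm_electrodes),
                x$sm_params$sampling_rate))
  if (length(x$units)) cat(sprintf("; %d units", length(x$units)))
  cat("\n")
  invisible(x)
}

#' Recording duration of the full-frame stream, seconds
#' @param rec a `dual_mode_recording`.
#' @export
recording_duration <- function(rec) ncol(rec$aps) / rec$aps_params$sampling_rate

## ---- on-disk container -----------------------------------------------------
## Directory layout (text manifest + raw int16 chunks):
##   manifest.json                 format tag, per-stream attrs, chunking
##   geometry.csv                  id,x_um,y_um (17 significant digits)
##   aps/chunk-000001.bin ...      int16 little-endian, electrode-major
##   sm/chunk-000001.bin           (column within a chunk = one frame)
##   units/unit_<k>.csv            spike_time_s
##   ground_truth/*.csv            simulator truth tables (optional)

write_int16_chunks <- function(mat, dir, lsb_uv, frames_per_chunk) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- ncol(mat)
  starts <- seq(1L, n, by = frames_per_chunk)
  for (k in seq_along(starts)) {
    i0 <- starts[k]; i1 <- min(i0 + frames_per_chunk - 1L, n)
    v <- round(mat[, i0:i1, drop = FALSE] / lsb_uv)
    v <- pmin(pmax(v, -32768), 32767)
    con <- file(file.path(dir, sprintf("chunk-%06d.bin", k)), "wb")
    writeBin(as.integer(v), con, size = 2L, endian = "little")
    close(con)
  }
  length(starts)
}

read_int16_chunks <- function(dir, lsb_uv, n_rows, n_frames, frames_per_chunk,
                              n_chunks) {
  out <- matrix(0, n_rows, n_frames)
  at <- 1L
  for (k in seq_len(n_chunks)) {
    f <- file.path(dir, sprintf("chunk-%06d.bin", k))
    if (!file.exists(f)) stop("format error: missing chunk ", f)
    nf <- min(frames_per_chunk, n_frames - at + 1L)
    con <- file(f, "rb")
    v <- readBin(con, "integer", n = n_rows * nf, size = 2L, signed = TRUE,
                 endian = "little")
    close(con)
    if (length(v) != n_rows * nf)
      stop("format error: truncated chunk ", f)
    out[, at:(at + nf - 1L)] <- v * lsb_uv
    at <- at + nf
  }
  out
}

#' Write a dual-mode recording to a chunked on-disk container
#'
#' The container is a directory with a JSON manifest, a full-precision CSV
#' geometry table, and the sample streams stored as 16-bit integers (with an
#' explicit uV-per-LSB scale) in electrode-major chunks of at most
#' `chunk_s` seconds, so full-array recordings can be written and read in
#' bounded memory. The write -> read round trip is bit-exact for the stored
#' integer samples and exact for all metadata.
#'
#' @param rec a `dual_mode_recording`.
#' @param path container directory (created; must not already contain a
#'   manifest).
#' @param lsb_uv uV per least-significant bit for int16 quantization.
#' @param chunk_s chunk length in seconds (<= 1 recommended).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, lsb_uv = 0.1, chunk_s = 1) {
  stopifnot(inherits(rec, "dual_mode_recording"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  write_geometry_csv(rec$array, file.path(path, "geometry.csv"))
  fpc_aps <- max(1L, as.integer(round(chunk_s * rec$aps_params$sampling_rate)))
  n_chunks_aps <- write_int16_chunks(rec$aps, file.path(path, "aps"),
                                     lsb_uv, fpc_aps)
  manifest <- list(
    format = "dmrec-1",
    aps = list(sampling_rate_hz = rec$aps_params$sampling_rate,
               noise_rms_uv = rec$aps_params$noise_rms,
               lsb_uv = lsb_uv, t0_s = rec$t0,
               n_electrodes = nrow(rec$aps), n_frames = ncol(rec$aps),
               frames_per_chunk = fpc_aps, n_chunks = n_chunks_aps)
  )
  if (length(rec$sm_electrodes)) {
    fpc_sm <- max(1L, as.integer(round(chunk_s * rec$sm_params$sampling_rate)))
    n_chunks_sm <- write_int16_chunks(rec$sm, file.path(path, "sm"),
                                      lsb_uv, fpc_sm)
    manifest$sm <- list(sampling_rate_hz = rec$sm_params$sampling_rate,
                        noise_rms_uv = rec$sm_params$noise_rms,
                        lsb_uv = lsb_uv, t0_s = rec$t0,
                        electrode_ids = rec$sm_electrodes,
                        n_electrodes = nrow(rec$sm), n_frames = ncol(rec$sm),
                        frames_per_chunk = fpc_sm, n_chunks = n_chunks_sm)
  }
  if (length(rec$units)) {
    dir.create(file.path(path, "units"), showWarnings = FALSE)
    for (u in names(rec$units)) {
      utils::write.csv(
        data.frame(spike_time_s = sprintf("%.17g", rec$units[[u]])),
        file.path(path, "units", paste0("unit_", u, ".csv")),
        row.names = FALSE, quote = FALSE)
    }
    manifest$units <- names(rec$units)
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a dual-mode recording container
#'
#' @param path container directory written by [write_recording()].
#' @return a `dual_mode_recording` (samples in uV).
#' @export
read_recording <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("format error: missing manifest.json in ", path)
  m <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(m$format) || m$format != "dmrec-1")
    stop("format error: missing or unknown format tag")
  array <- read_geometry_csv(file.path(path, "geometry.csv"))
  a <- m$aps
  if (is.null(a)) stop("format error: missing aps group")
  need <- c("sampling_rate_hz", "lsb_uv", "t0_s", "n_electrodes", "n_frames",
            "frames_per_chunk", "n_chunks")
  miss <- setdiff(need, names(a))
  if (length(miss)) stop("format error: aps attrs missing ",
                         paste(miss, collapse = ", "))
  aps <- read_int16_chunks(file.path(path, "aps"), a$lsb_uv, a$n_electrodes,
                           a$n_frames, a$frames_per_chunk, a$n_chunks)
  aps_params <- mode_params("full_frame", a$sampling_rate_hz,
                            a$noise_rms_uv %||% 10.4)
  sm <- NULL; sm_params <- NULL; sm_electrodes <- integer(0)
  if (!is.null(m$sm)) {
    s <- m$sm
    miss <- setdiff(c(need, "electrode_ids"), names(s))
    if (length(miss)) stop("format error: sm attrs missing ",
                           paste(miss, collapse = ", "))
    sm <- read_int16_chunks(file.path(path, "sm"), s$lsb_uv, s$n_electrodes,
                            s$n_frames, s$frames_per_chunk, s$n_chunks)
    sm_params <- mode_params("high_snr", s$sampling_rate_hz,
                             s$noise_rms_uv %||% 3.0)
    sm_electrodes <- as.integer(s$electrode_ids)
  }
  units <- NULL
  if (!is.null(m$units)) {
    units <- lapply(as.character(m$units), function(u) {
      f <- file.path(path, "units", paste0("unit_", u, ".csv"))
      if (!file.exists(f)) stop("format error: missing unit file ", f)
      as.numeric(utils::read.csv(f)$spike_time_s)
    })
    names(units) <- as.character(m$units)
  }
  dual_mode_recording(aps, aps_params, array, sm, sm_params, sm_electrodes,
                      t0 = a$t0_s, units = units)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
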