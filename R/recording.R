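#' Construct a two-channel nerve recording
#'
#' Container for simultaneously acquired spinal-nerve (SN) and dorsal-root
#' (DR) extracellular voltage traces, with an optional synchronized force
#' stimulus channel (grams) and acquisition/geometry metadata.
#'
#' @param sn_trace Numeric vector, SN voltage trace (arbitrary units).
#' @param dr_trace Numeric vector, DR voltage trace; same length as `sn_trace`.
#' @param force_trace Optional numeric vector of applied force in grams,
#'   sampled on the same clock (same length), or `NULL`.
#' @param sampling_rate Samples per second (default 30000).
#' @param electrode_distance Distance between the SN and DR hook electrodes
#'   in meters (default 0.004).
#' @param channel_meta Free-form list of channel labels/metadata.
#'
#' @return An object of class `"recording"`.
#' @export
recording <- function(sn_trace, dr_trace, force_trace = NULL,
                      sampling_rate = 30000, electrode_distance = 0.004,
                      channel_meta = list()) {
  sn_trace <- as.numeric(sn_trace)
  dr_trace <- as.numeric(dr_trace)
  if (length(sn_trace) != length(dr_trace))
    stop("sn_trace and dr_trace must have identical length")
  if (!is.null(force_trace)) {
    force_trace <- as.numeric(force_trace)
    if (length(force_trace) != length(sn_trace))
      stop("force_trace must have the same length as the voltage traces")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number")
  if (!is.numeric(electrode_distance) || length(electrode_distance) != 1L ||
      !is.finite(electrode_distance) || electrode_distance <= 0)
    stop("electrode_distance must be a single positive number")
  structure(list(
    sn_trace = sn_trace, dr_trace = dr_trace, force_trace = force_trace,
    sampling_rate = sampling_rate, electrode_distance = electrode_distance,
    channel_meta = channel_meta
  ), class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  n <- length(x$sn_trace)
  cat(sprintf(
    "<recording> %d samples (%.2f s at %g Hz), electrode distance %g m, force channel: %s\n",
    n, n / x$sampling_rate, x$sampling_rate, x$electrode_distance,
    if (is.null(x$force_trace)) "absent" else "present"))
  invisible(x)
}

is_recording <- function(x) inherits(x, "recording")

#' Validate a recording, stopping on invariant violations
#' @param rec A `recording` object.
#' @return `rec`, invisibly.
#' @export
validate_recording <- function(rec) {
  if (!is_recording(rec)) stop("not a recording object")
  # reconstructing through the constructor re-checks every invariant
  recording(rec$sn_trace, rec$dr_trace, rec$force_trace,
            rec$sampling_rate, rec$electrode_distance, rec$channel_meta)
  invisible(rec)
}

sidecar_path <- function(path) paste0(path, ".meta.yaml")

#' Read a recording from disk
#'
#' Two on-disk formats are supported. `"delimited"` is a CSV/TSV with header
#' columns `time,sn,dr` and optionally `force`; the time column must be
#' uniformly sampled (relative jitter below 1e-6). `"flatbin"` is a flat
#' binary of interleaved 32-bit floats with a structured-text sidecar
#' (`<path>.meta.yaml`) giving `channels` (order), `sampling_rate` and
#' `electrode_distance`.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"flatbin"`, `"delimited"`. `"auto"`
#'   chooses `flatbin` when a sidecar file exists.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("auto", "flatbin", "delimited")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (file.exists(sidecar_path(path))) "flatbin" else "delimited"
  if (format == "flatbin") read_recording_flatbin(path) else read_recording_delimited(path)
}

read_recording_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path)
  need <- c("time", "sn", "dr")
  if (!all(need %in% names(dt)))
    stop("delimited recording must have columns time, sn, dr (got: ",
         paste(names(dt), collapse = ", "), ")")
  tm <- as.numeric(dt$time)
  if (length(tm) < 2L) stop("recording must contain at least 2 samples")
  dts <- diff(tm)
  dt0 <- stats::median(dts)
  if (dt0 <= 0 || any(abs(dts - dt0) > 1e-6 * dt0))
    stop("time column is not uniformly sampled (format error)")
  fs <- 1 / dt0
  recording(dt$sn, dt$dr,
            force_trace = if ("force" %in% names(dt)) dt$force else NULL,
            sampling_rate = fs)
}

read_recording_flatbin <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing sidecar metadata file for flat binary recording: ", sc)
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- yaml::read_yaml(sc)
  for (k in c("channels", "sampling_rate", "electrode_distance"))
    if (is.null(meta[[k]])) stop("sidecar missing required key: ", k)
  ch <- unlist(meta$channels)
  nch <- length(ch)
  raw_n <- file.size(path) / 4L
  if (raw_n %% nch != 0)
    stop("flat binary length is not a multiple of the channel count (format error)")
  vals <- readBin(path, what = "numeric", size = 4L, n = raw_n,
                  endian = "little")
  m <- matrix(vals, ncol = nch, byrow = TRUE)
  colnames(m) <- ch
  if (!all(c("sn", "dr") %in% ch))
    stop("sidecar channels must include 'sn' and 'dr'")
  recording(m[, "sn"], m[, "dr"],
            force_trace = if ("force" %in% ch) m[, "force"] else NULL,
            sampling_rate = meta$sampling_rate,
            electrode_distance = meta$electrode_distance,
            channel_meta = meta$channel_meta %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a recording to disk
#'
#' @param rec A [recording()].
#' @param path Output path.
#' @param format `"flatbin"` (interleaved float32 + YAML sidecar) or
#'   `"delimited"` (CSV with time, sn, dr and optional force columns).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, format = c("flatbin", "delimited")) {
  format <- match.arg(format)
  validate_recording(rec)
  if (format == "delimited") {
    n <- length(rec$sn_trace)
    dt <- data.table::as.data.table(
      c(list(time = (seq_len(n) - 1) / rec$sampling_rate,
             sn = rec$sn_trace, dr = rec$dr_trace),
        if (!is.null(rec$force_trace)) list(force = rec$force_trace)))
    data.table::fwrite(dt, path)
  } else {
    ch <- c("sn", "dr", if (!is.null(rec$force_trace)) "force")
    m <- cbind(rec$sn_trace, rec$dr_trace,
               if (!is.null(rec$force_trace)) rec$force_trace)
    writeBin(as.numeric(t(m)), path, size = 4L, endian = "little")
    yaml::write_yaml(list(channels = as.list(ch),
                          sampling_rate = rec$sampling_rate,
                          electrode_distance = rec$electrode_distance,
                          n_samples = length(rec$sn_trace)),
                     sidecar_path(path))
  }
  invisible(path)
}

#' Write an event table (spike train, match table or summary) to CSV
#'
#' One row per event or spike pair; spike times round-trip through
#' [read_events()] to better than 1e-9 s. Waveform matrices are not written
#' here (they live in the `spike_train` object / flat binaries).
#'
#' @param x A `spike_train`, `match_table`, or data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(x, path) {
  df <- if (inherits(x, "spike_train")) {
    data.frame(time_s = x$times, channel = rep(x$channel, length(x$times)),
               prominence = x$prominences)
  } else if (inherits(x, "match_table")) {
    x$pairs
  } else if (is.data.frame(x)) {
    x
  } else stop("unsupported type for write_events")
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read an event table written by [write_events()]
#' @param path CSV path.
#' @return A data frame.
#' @export
read_events <- function(path) {
  as.data.frame(data.table::fread(path))
}
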