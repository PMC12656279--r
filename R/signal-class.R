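#' Uniformly sampled single-channel signal
#'
#' Lightweight container for a uniformly sampled waveform: amplitude samples
#' (arbitrary units), sampling rate `fs` in Hz, and start time `t0` in
#' seconds. All generators and filters in this package consume and return
#' `hrv_signal` objects.
#'
#' @param samples numeric vector of finite amplitudes (a.u.)
#' @param fs sampling rate in Hz, > 0
#' @param t0 time of the first sample in seconds
#' @return an object of class `hrv_signal`
#' @export
hrv_signal <- function(samples, fs, t0 = 0) {
  stopifnot(is.numeric(samples), length(fs) == 1L, fs > 0, is.finite(fs),
            length(t0) == 1L, is.finite(t0))
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("signal samples must be finite")
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs),
                 t0 = as.numeric(t0)),
            class = "hrv_signal")
}

#' @export
print.hrv_signal <- function(x, ...) {
  cat(sprintf("<hrv_signal> %d samples @ %g Hz, t0 = %g s (%.2f s)\n",
              length(x$samples), x$fs, x$t0, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.hrv_signal <- function(x) length(x$samples)

#' Sample times of a signal
#' @param x an `hrv_signal`
#' @return numeric vector of sample times in seconds
#' @export
signal_times <- function(x) {
  stopifnot(inherits(x, "hrv_signal"))
  x$t0 + (seq_along(x$samples) - 1) / x$fs
}

#' Duration of a signal in seconds
#' @param x an `hrv_signal`
#' @export
signal_duration <- function(x) length(x$samples) / x$fs

#' Write a signal as two-column delimited text with a JSON sidecar
#'
#' The data file holds `time_s` and `value` columns; the sidecar
#' (`<path>.json`) records the sampling rate, units and any identifiers so
#' the file is self-describing.
#'
#' @param x an `hrv_signal`
#' @param path output path for the delimited text file
#' @param meta optional named list merged into the sidecar (ids, seed, ...)
#' @return `path`, invisibly
#' @export
write_signal <- function(x, path, meta = list()) {
  stopifnot(inherits(x, "hrv_signal"))
  df <- data.frame(time_s = signal_times(x), value = x$samples)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  side <- c(list(fs = x$fs, t0 = x$t0, n = length(x$samples), units = "a.u."),
            meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a signal written by [write_signal()]
#' @param path path to the delimited text file (sidecar `<path>.json` must exist)
#' @return an `hrv_signal`
#' @export
read_signal <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  hrv_signal(df$value, fs = side$fs, t0 = side$t0)
}

# Scoped RNG: run `expr` under `seed` without disturbing the caller's RNG
# stream, so every stochastic operation is a pure function of (spec, seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-seed derivation, kept inside 32-bit integer range.
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(seed) %% 2147483647
  for (k in ids) s <- (s * 7919 + as.double(k) * 104729 + 13) %% 2147483647
  as.integer(s)
}
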