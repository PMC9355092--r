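#' Mono vibration waveform
#'
#' The common currency of all signal operations in the package: a uniformly
#' sampled mono waveform with a sample rate, as picked up from a rice stem by
#' a contact transducer. Amplitudes are dimensionless with a nominal range of
#' \[-1, 1\].
#'
#' @param samples Numeric vector of finite amplitudes.
#' @param sample_rate Sampling rate in Hz (positive).
#' @param label Optional signal-class tag (e.g. \code{"female_courtship"},
#'   \code{"PT225"}).
#' @return An object of class \code{wave_signal}: a list with elements
#'   \code{samples}, \code{sample_rate} and \code{label}.
#' @examples
#' w <- wave_signal(sin(2 * pi * 225 * (0:7999) / 8000), 8000, label = "PT225")
#' wave_duration(w)
#' @export
wave_signal <- function(samples, sample_rate, label = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop("wave_signal: 'samples' must be non-empty")
  if (!all(is.finite(samples)))
    stop("wave_signal: all samples must be finite")
  sample_rate <- as.numeric(sample_rate)
  if (length(sample_rate) != 1L || !is.finite(sample_rate) || sample_rate <= 0)
    stop("wave_signal: 'sample_rate' must be a single positive number")
  structure(
    list(samples = samples, sample_rate = sample_rate, label = label),
    class = "wave_signal"
  )
}

#' @export
print.wave_signal <- function(x, ...) {
  cat(sprintf(
    "wave_signal: %d samples @ %g Hz (%.3f s)%s\n",
    length(x$samples), x$sample_rate, wave_duration(x),
    if (!is.null(x$label)) paste0(" [", x$label, "]") else ""
  ))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w A \code{wave_signal}.
#' @return Duration in seconds.
#' @export
wave_duration <- function(w) {
  stopifnot(inherits(w, "wave_signal"))
  length(w$samples) / w$sample_rate
}

#' Root-mean-square amplitude of a waveform
#' @param w A \code{wave_signal}.
#' @return RMS amplitude (dimensionless).
#' @export
wave_rms <- function(w) {
  stopifnot(inherits(w, "wave_signal"))
  sqrt(mean(w$samples^2))
}

#' Extract a sample interval from a waveform
#'
#' Intervals follow the package-wide convention: 0-based, half-open
#' \code{[start, end)} sample indices, as used for segmentation boundaries.
#'
#' @param w A \code{wave_signal}.
#' @param start,end 0-based half-open sample interval.
#' @return A \code{wave_signal} holding samples \code{start..end-1}.
#' @export
wave_slice <- function(w, start, end) {
  stopifnot(inherits(w, "wave_signal"))
  n <- length(w$samples)
  if (start < 0 || end > n || end <= start)
    stop(sprintf("wave_slice: invalid interval [%s, %s) for %d samples",
                 format(start), format(end), n))
  wave_signal(w$samples[(start + 1L):end], w$sample_rate, label = w$label)
}

#' Ground-truth parameters attached to a generated waveform
#'
#' Synthetic-signal generators attach the parameters actually drawn for each
#' individual (carrier frequency, pulse rate, part boundaries, pulse counts)
#' so that estimator tests can close the recovery loop.
#'
#' @param w A generated \code{wave_signal}.
#' @return A list of true parameters, or \code{NULL} for waveforms that were
#'   not produced by a generator.
#' @export
signal_truth <- function(w) {
  stopifnot(inherits(w, "wave_signal"))
  attr(w, "truth", exact = TRUE)
}

# internal: attach truth metadata without copying semantics surprises
set_truth <- function(w, truth) {
  attr(w, "truth") <- truth
  w
}
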