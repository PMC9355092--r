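#' Oscillogram and spectrogram of a waveform
#'
#' Two-panel figure in the style of bioacoustics signal atlases: the
#' time-domain amplitude trace on top and a spectrogram (frequency axis
#' limited to the vibration band, 0-500 Hz by default) below. Rendered to
#' the active device, or to a PNG when \code{path} is given.
#'
#' @param w A [wave_signal()].
#' @param path Optional PNG output path.
#' @param flim Spectrogram frequency limits, Hz.
#' @param window_s Spectrogram analysis window, seconds.
#' @param width,height PNG size in pixels.
#' @return \code{path} (or \code{NULL} when drawing to the active device),
#'   invisibly.
#' @export
plot_oscillogram_spectrogram <- function(w, path = NULL, flim = c(0, 500),
                                         window_s = 0.064, width = 800,
                                         height = 600) {
  stopifnot(inherits(w, "wave_signal"))
  if (length(w$samples) < 16) stop("plot_oscillogram_spectrogram: signal too short")
  if (!is.null(path)) {
    grDevices::png(path, width = width, height = height)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)

  t <- (seq_along(w$samples) - 1) / w$sample_rate
  graphics::plot(t, w$samples, type = "l", xlab = "Time (s)",
                 ylab = "Amplitude",
                 main = if (!is.null(w$label)) w$label else "Oscillogram")

  nw <- min(next_pow2(window_s * w$sample_rate), length(w$samples))
  sg <- signal::specgram(w$samples, n = nw, Fs = w$sample_rate,
                         overlap = floor(nw / 2))
  keep <- sg$f >= flim[1] & sg$f <= flim[2]
  graphics::image(x = sg$t, y = sg$f[keep],
                  z = t(20 * log10(Mod(sg$S[keep, , drop = FALSE]) + 1e-12)),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "Time (s)", ylab = "Frequency (Hz)",
                  main = "Spectrogram")
  invisible(path)
}
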