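# Stimulus waveforms: the time course of the electrode drive. A waveform
# evaluates to a dimensionless multiple of 1 V at any time; the field
# solution for a unit drive supplies the spatial profile.
#
# Polarity convention: pulses are named after the phase of the distant
# return electrode, as is customary for the implant. A "cathodic" pulse
# therefore drives the working electrode positive and depolarises the
# axon-terminal end of a cell standing perpendicular on the array, while
# an "anodic" pulse hyperpolarises it.

.polarity_sign <- function(polarity) {
  switch(match.arg(polarity, c("cathodic", "anodic")),
         cathodic = 1, anodic = -1)
}

.piecewise_waveform <- function(durations, amplitudes, label) {
  stopifnot(all(durations > 0), length(durations) == length(amplitudes))
  structure(list(type = "piecewise",
                 segments = data.frame(duration = durations,
                                       amplitude = amplitudes),
                 total = sum(durations), label = label),
            class = "cbc_waveform")
}

#' Monophasic rectangular pulse
#'
#' @param amplitude Pulse amplitude, V (positive number).
#' @param width Pulse width, ms.
#' @param polarity `"cathodic"` (depolarises the terminals in the
#'   subretinal geometry) or `"anodic"`.
#' @return Object of class `cbc_waveform`.
#' @examples
#' monophasic(1, 1, "cathodic") # the standard pulse
#' @export
monophasic <- function(amplitude, width, polarity = "cathodic") {
  if (width <= 0) stop("width must be positive")
  s <- .polarity_sign(polarity)
  .piecewise_waveform(width, s * amplitude,
                      sprintf("monophasic %s %g V / %g ms", polarity,
                              amplitude, width))
}

#' Charge-balanced biphasic pulse
#'
#' Two opposite-polarity rectangular phases. The split parameter `x` gives
#' the first phase `x` percent of the total width; the second phase's
#' amplitude is scaled by `x/(100-x)` so the two phase areas (charges) are
#' equal, making the time integral of every biphasic pulse exactly zero.
#'
#' @param amplitude First-phase amplitude, V.
#' @param total_width Total pulse width, ms.
#' @param x First-phase share of the width, percent, strictly in (0, 100).
#' @param order `"cathodic_first"` or `"anodic_first"`.
#' @return Object of class `cbc_waveform`.
#' @export
biphasic <- function(amplitude, total_width, x = 50,
                     order = c("cathodic_first", "anodic_first")) {
  order <- match.arg(order)
  if (total_width <= 0) stop("total_width must be positive")
  if (x <= 0 || x >= 100) stop("x must be strictly between 0 and 100")
  s <- if (order == "cathodic_first") 1 else -1
  d1 <- total_width * x / 100
  d2 <- total_width - d1
  a2 <- amplitude * x / (100 - x)
  .piecewise_waveform(c(d1, d2), c(s * amplitude, -s * a2),
                      sprintf("biphasic %s %g V / %g ms, x = %g%%",
                              order, amplitude, total_width, x))
}

#' Pulse burst
#'
#' `n` copies of a pulse separated by `isi` ms of zero drive.
#'
#' @param pulse A piecewise `cbc_waveform`.
#' @param n Number of pulses (>= 1).
#' @param isi Inter-stimulus interval, ms.
#' @return Object of class `cbc_waveform`.
#' @export
burst <- function(pulse, n, isi) {
  stopifnot(inherits(pulse, "cbc_waveform"), pulse$type == "piecewise")
  if (n < 1) stop("n must be >= 1")
  if (isi < 0) stop("isi must be non-negative")
  seg <- pulse$segments
  if (n == 1) return(pulse)
  dur <- seg$duration; amp <- seg$amplitude
  if (isi > 0) {
    dur <- c(rep(c(dur, isi), n - 1), dur)
    amp <- c(rep(c(amp, 0), n - 1), amp)
  } else {
    dur <- rep(dur, n); amp <- rep(amp, n)
  }
  .piecewise_waveform(dur, amp,
                      sprintf("burst of %d x [%s], isi %g ms", n,
                              pulse$label, isi))
}

#' Sinusoidal stimulus
#'
#' `amplitude * sin(2 pi f t)` for `n_cycles` full cycles.
#'
#' @param freq Frequency, Hz.
#' @param amplitude Amplitude, V.
#' @param n_cycles Number of cycles.
#' @return Object of class `cbc_waveform`.
#' @export
sinusoid <- function(freq, amplitude = 1, n_cycles = 1) {
  if (freq <= 0) stop("freq must be positive")
  structure(list(type = "sine", freq = freq, amplitude = amplitude,
                 total = n_cycles * 1000 / freq,
                 label = sprintf("sinusoid %g Hz x %g cycles", freq, n_cycles)),
            class = "cbc_waveform")
}

#' Evaluate a waveform
#'
#' Pure function of time: the drive (in V) at each requested time; zero
#' outside `[0, total_duration]`.
#'
#' @param w A `cbc_waveform`.
#' @param t Time(s), ms.
#' @return Drive value(s), V.
#' @export
waveform_value <- function(w, t) {
  stopifnot(inherits(w, "cbc_waveform"))
  out <- numeric(length(t))
  inside <- t >= 0 & t <= w$total
  if (w$type == "sine") {
    out[inside] <- w$amplitude * sin(2 * pi * w$freq * t[inside] / 1000)
  } else {
    edges <- cumsum(w$segments$duration)
    idx <- findInterval(t[inside], c(0, edges), left.open = TRUE,
                        rightmost.closed = TRUE)
    idx[idx == 0] <- 1L # t = 0 belongs to the first segment
    out[inside] <- w$segments$amplitude[pmin(idx, nrow(w$segments))]
  }
  out
}

#' Time integral of a waveform
#'
#' Signed area in V ms; identically zero for charge-balanced biphasic
#' pulses and for sinusoids over whole cycles.
#'
#' @param w A `cbc_waveform`.
#' @return Integral in V ms.
#' @export
waveform_integral <- function(w) {
  if (w$type == "sine") {
    f <- w$freq / 1000 # cycles per ms
    w$amplitude * (1 - cos(2 * pi * f * w$total)) / (2 * pi * f)
  } else {
    sum(w$segments$duration * w$segments$amplitude)
  }
}

#' Offset time of the last active segment
#'
#' The end of the last segment with non-zero amplitude (for sinusoids, the
#' total duration); decay times are measured from this instant.
#'
#' @param w A `cbc_waveform`.
#' @return Time in ms.
#' @export
waveform_offset <- function(w) {
  if (w$type == "sine") return(w$total)
  act <- which(w$segments$amplitude != 0)
  if (length(act) == 0) return(0)
  sum(w$segments$duration[seq_len(max(act))])
}

#' @export
print.cbc_waveform <- function(x, ...) {
  cat(sprintf("<cbc_waveform> %s (%.3g ms total)\n", x$label, x$total))
  invisible(x)
}

#' @export
plot.cbc_waveform <- function(x, n = 1000, ...) {
  t <- seq(0, x$total * 1.2, length.out = n)
  plot(t, waveform_value(x, t), type = "s", xlab = "time (ms)",
       ylab = "drive (V)", main = x$label, ...)
  abline(h = 0, lty = 3)
  invisible(x)
}

#' Read a stimulus protocol from a YAML file
#'
#' Schema: `type` (monophasic / biphasic / burst / sinusoid) plus the
#' constructor arguments `amplitude_V`, `width_ms`, `polarity`,
#' `x_percent`, `order`, `n_pulses`, `isi_ms`, `freq_Hz`, `n_cycles`. A burst
#' nests its unit pulse under `pulse:`.
#'
#' @param path YAML file path.
#' @return A `cbc_waveform`.
#' @export
read_protocol_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  build <- function(cfg) {
    switch(cfg$type,
      monophasic = monophasic(cfg$amplitude_V, cfg$width_ms,
                              cfg$polarity %||% "cathodic"),
      biphasic = biphasic(cfg$amplitude_V, cfg$width_ms,
                          cfg$x_percent %||% 50,
                          cfg$order %||% "cathodic_first"),
      burst = burst(build(cfg$pulse), cfg$n_pulses, cfg$isi_ms),
      sinusoid = sinusoid(cfg$freq_Hz, cfg$amplitude_V %||% 1,
                          cfg$n_cycles %||% 1),
      stop("unknown protocol type: ", cfg$type))
  }
  build(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
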