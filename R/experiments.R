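# Scripted in-silico experiments: standard pulses, axon-length sweeps,
# electrode position maps, calcium decay times, channel swaps and the
# mono-compartment sinusoidal frequency response.

#' Standard stimulation run
#'
#' Builds the system for a cell, applies a stimulus waveform through the
#' solved field and summarises the response: per-region polarisation and,
#' for active runs, peak terminal calcium and its decay time.
#'
#' @param cell A `cbc_cell`.
#' @param field A `cbc_field` solved for the standard volume/electrode.
#' @param protocol A `cbc_waveform` (default: the standard 1 V / 1 ms
#'   cathodic pulse).
#' @param active Include the terminal calcium channel.
#' @param channel Optional channel override (see [assemble()]).
#' @param placement Placement arguments, see [assemble()].
#' @param dt Time step, ms.
#' @param t_end Simulated time, ms (default waveform + 15 ms).
#' @param record_stride Recording stride.
#' @return Object of class `cbc_experiment` with `summary` (data frame)
#'   and `trace`.
#' @export
run_standard <- function(cell, field, protocol = monophasic(1, 1, "cathodic"),
                         active = TRUE, channel = NULL, placement = list(),
                         dt = 0.01, t_end = NULL, record_stride = 5L) {
  sys <- assemble(cell, field, channel = channel, placement = placement,
                  passive = !active)
  if (is.null(t_end))
    t_end <- (if (is.null(protocol)) 0 else protocol$total) + 15
  tr <- advance(sys, protocol, dt = dt, t_end = t_end,
                record_stride = record_stride)
  rs <- region_summary(tr)
  term <- tr$region == "terminal"
  summary <- data.frame(
    cell_type = cell$spec$cell_type,
    active = active,
    channel = if (active) sys$channel$type else NA_character_,
    protocol = if (is.null(protocol)) "none" else protocol$label,
    terminal_depol = rs$max_depol[rs$region == "terminal"],
    dendrite_hyperpol = rs$max_hyperpol[rs$region == "dendrite"],
    peak_ca = if (active) max(tr$ca[, term]) else NA_real_,
    decay_ms = if (active) ca_decay_time(tr)$decay_ms else NA_real_)
  structure(list(summary = summary, trace = tr, regions = rs,
                 system = sys),
            class = "cbc_experiment")
}

#' @export
print.cbc_experiment <- function(x, ...) {
  cat("<cbc_experiment>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Time for terminal calcium to return to baseline
#'
#' Measures, from the offset of the last active stimulus segment, how long
#' the maximum terminal calcium concentration stays more than
#' `rel_threshold` above its pre-stimulus baseline. A trace that never
#' exceeds the threshold gives 0 ms; a trace still above it at the end is
#' flagged as censored.
#'
#' @param trace A `cbc_trace` containing terminal compartments.
#' @param rel_threshold Relative excess over baseline that counts as
#'   recovered (default 2 percent).
#' @return List with `decay_ms`, `censored` and `baseline_uM`.
#' @export
ca_decay_time <- function(trace, rel_threshold = 0.02) {
  term <- trace$region == "terminal"
  if (!any(term)) stop("trace has no terminal compartments")
  ca <- apply(trace$ca[, term, drop = FALSE], 1, max)
  base <- ca[1]
  thr <- base * (1 + rel_threshold)
  above <- ca > thr
  if (!any(above))
    return(list(decay_ms = 0, censored = FALSE, baseline_uM = base))
  last <- max(which(above))
  censored <- last == length(ca)
  t_rec <- if (censored) max(trace$time) else trace$time[last + 1]
  list(decay_ms = max(0, t_rec - trace$offset),
       censored = censored, baseline_uM = base)
}

#' Axon-length sweep
#'
#' Re-runs the standard protocol on copies of the cell whose axonal and
#' terminal z-extent is rescaled by each factor (see [scale_axon()]),
#' collecting the per-factor polarisation (and calcium, if active).
#'
#' @param cell A `cbc_cell`.
#' @param field A `cbc_field`.
#' @param factors Scale factors (default 100 percent down to 20 percent
#'   in 10 percent increments).
#' @param protocol Stimulus waveform.
#' @param active Active or passive membrane.
#' @param ... Passed to [run_standard()].
#' @return Object of class `cbc_sweep`: data frame with one row per
#'   factor, plus the runs.
#' @export
axon_length_sweep <- function(cell, field, factors = seq(1, 0.2, by = -0.1),
                              protocol = monophasic(1, 1, "cathodic"),
                              active = FALSE, ...) {
  runs <- lapply(factors, function(f)
    run_standard(scale_axon(cell, f), field, protocol, active = active, ...))
  tab <- do.call(rbind, lapply(runs, function(r) r$summary))
  tab <- cbind(factor = factors, tab)
  structure(list(table = tab, runs = runs), class = "cbc_sweep")
}

#' @export
print.cbc_sweep <- function(x, ...) {
  cat("<cbc_sweep>\n")
  print(x$table[, c("factor", "terminal_depol", "dendrite_hyperpol",
                    "peak_ca")], row.names = FALSE)
  invisible(x)
}

#' Electrode position map of peak terminal calcium
#'
#' Re-runs a protocol with the cell shifted laterally (x) and axially (z)
#' relative to the electrode on a regular grid (default pitch 2 um) and
#' records the maximum terminal calcium per position.
#'
#' @param cell A `cbc_cell`.
#' @param field A `cbc_field`.
#' @param protocol Stimulus waveform.
#' @param x_range,z_range Inclusive shift ranges, um (defaults give the
#'   48 x 17 = 816-position map).
#' @param step Grid pitch, um.
#' @param ... Passed to [run_standard()].
#' @return Object of class `cbc_position_map`: matrix `peak_ca`
#'   (x index by z index) with axes `dx`, `dz`.
#' @export
position_map <- function(cell, field, protocol = monophasic(1, 1, "cathodic"),
                         x_range = c(-47, 47), z_range = c(0, 32), step = 2,
                         ...) {
  dxs <- seq(x_range[1], x_range[2], by = step)
  dzs <- seq(z_range[1], z_range[2], by = step)
  peak <- matrix(NA_real_, length(dxs), length(dzs))
  for (j in seq_along(dzs))
    for (i in seq_along(dxs)) {
      r <- run_standard(cell, field, protocol, active = TRUE,
                        placement = list(dx = dxs[i], dz = dzs[j]), ...)
      peak[i, j] <- r$summary$peak_ca
    }
  structure(list(peak_ca = peak, dx = dxs, dz = dzs,
                 cell_type = cell$spec$cell_type,
                 protocol = protocol$label),
            class = "cbc_position_map")
}

#' @export
print.cbc_position_map <- function(x, ...) {
  cat(sprintf("<cbc_position_map> %s, %d x %d positions (%d total)\n",
              x$cell_type, length(x$dx), length(x$dz),
              length(x$peak_ca)))
  cat(sprintf("  peak terminal [Ca]_i %.3g .. %.3g uM\n",
              min(x$peak_ca), max(x$peak_ca)))
  invisible(x)
}

#' @export
plot.cbc_position_map <- function(x, ...) {
  image(x$dx, x$dz, x$peak_ca, col = hcl.colors(64, "viridis"),
        xlab = "x shift (um)", ylab = "z shift (um)",
        main = sprintf("peak [Ca]_i (uM), %s", x$cell_type), ...)
  invisible(x)
}

#' Identical channel equipment on both cells
#'
#' Runs both cells with the same channel type on their terminals and
#' reports the per-cell peak terminal calcium under the given protocol.
#'
#' @param cells List of `cbc_cell` (typically ON and OFF fixtures).
#' @param field A `cbc_field`.
#' @param channel The `cbc_channel` to place on every cell.
#' @param protocol Stimulus waveform.
#' @param ... Passed to [run_standard()].
#' @return Data frame with one row per cell.
#' @export
channel_swap <- function(cells, field, channel,
                         protocol = monophasic(1, 0.5, "cathodic"), ...) {
  do.call(rbind, lapply(cells, function(cl)
    run_standard(cl, field, protocol, active = TRUE, channel = channel,
                 ...)$summary))
}

#' Mono-compartment sinusoidal frequency response
#'
#' A single membrane patch (specific capacitance and leak) carrying one
#' calcium channel is driven by a sinusoidal current density across a
#' sweep of frequencies. For each frequency the peak inward channel
#' current over the last settled cycle is recorded; the curve is
#' normalised to its maximum and the frequency of maximal activation
#' reported.
#'
#' The default amplitude (3.75 uA/cm^2) polarises the patch by ~90 mV at
#' low frequency, reaching the activation range of both channel types;
#' see the package vignette for the rationale.
#'
#' @param channel A `cbc_channel`.
#' @param freqs Frequencies, Hz (default 19 log-spaced points, 1-1000 Hz).
#' @param amplitude Stimulus current density amplitude, uA/cm^2.
#' @param n_cycles Cycles simulated per frequency (the last one scored);
#'   at least 3 settled cycles precede the scored one by default.
#' @param dt Maximum time step, ms (refined to >= 200 steps per cycle).
#' @param s_over_v Surface-to-volume ratio of the patch, 1/um.
#' @return Object of class `cbc_freq_response`: data frame `table`
#'   (freq_Hz, peak_inward, normalized) and `argmax_Hz`.
#' @export
frequency_response <- function(channel,
                               freqs = 10^seq(0, 3, length.out = 19),
                               amplitude = 3.75, n_cycles = 6,
                               dt = 0.01, s_over_v = 4) {
  stopifnot(inherits(channel, "cbc_channel"), length(freqs) >= 1,
            n_cycles >= 4)
  cst <- cbc_constants()
  cal <- calcium_params()
  type <- if (channel$type == "T") 1L else 2L
  peak <- vapply(freqs, function(f) {
    period <- 1000 / f
    dtk <- min(dt, period / 200)
    nt <- ceiling(n_cycles * period / dtk)
    tt <- seq_len(nt) * dtk
    istim <- amplitude * sin(2 * pi * f * tt / 1000)
    out <- mono_cc_cpp(type, channel$gbar, channel$w, channel$e_k,
                       istim, dtk, s_over_v, cst$cm, cst$g_leak,
                       cst$e_leak, cal$ca_res, cal$tau, cal$ca_o, 1L)
    sel <- out$t >= (n_cycles - 1) * period
    max(pmax(-out$i[sel], 0))
  }, numeric(1))
  norm <- if (max(peak) > 0) peak / max(peak) else peak
  structure(list(table = data.frame(freq_Hz = freqs, peak_inward = peak,
                                    normalized = norm),
                 argmax_Hz = freqs[which.max(peak)],
                 channel = channel, amplitude = amplitude),
            class = "cbc_freq_response")
}

#' @export
print.cbc_freq_response <- function(x, ...) {
  cat(sprintf("<cbc_freq_response> %s-type, %d frequencies, argmax %.3g Hz\n",
              x$channel$type, nrow(x$table), x$argmax_Hz))
  invisible(x)
}

#' @export
plot.cbc_freq_response <- function(x, ...) {
  plot(x$table$freq_Hz, x$table$normalized, log = "x", type = "b", pch = 16,
       xlab = "frequency (Hz)", ylab = "normalised peak inward current",
       main = sprintf("%s-type frequency response", x$channel$type), ...)
  abline(v = x$argmax_Hz, lty = 3)
  invisible(x)
}
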