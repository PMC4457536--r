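# Assembly and integration of the multi-compartment system: capacitive,
# ionic and axial currents balance in every compartment; differences of
# the extracellular potential between neighbouring compartments drive the
# reduced membrane potential V = Vi - Ve - Vrest.

#' Assemble a simulation system
#'
#' Wires a cell into the cable equations: per-compartment capacitances and
#' absolute leak conductances, symmetric axial conductances
#' `1/(R_parent/2 + R_child/2)` between neighbours, the calcium channel on
#' the terminal (synaptic) compartments (L-type for the ON cell, T-type
#' for the OFF cell, overridable for channel-swap experiments), and the
#' unit-drive extracellular potential sampled at the placed compartment
#' centres (differences of which enter each compartment's equation, one
#' term per neighbour).
#'
#' @param cell A `cbc_cell`.
#' @param field A `cbc_field`, or `NULL` for a field-free system (zero
#'   extracellular drive; used for intrinsic-dynamics tests).
#' @param channel A `cbc_channel`, or `NULL` to choose by cell type.
#' @param placement List of [place_cell()] arguments (`dx`, `dy`, `dz`,
#'   `tip_distance`).
#' @param passive If `TRUE`, calcium conductances are set to zero.
#' @return Object of class `cbc_system`.
#' @export
assemble <- function(cell, field = NULL, channel = NULL,
                     placement = list(), passive = FALSE) {
  stopifnot(inherits(cell, "cbc_cell"))
  df <- cell$compartments
  n <- nrow(df)
  cst <- cbc_constants()
  if (is.null(channel))
    channel <- if (cell$spec$cell_type == "ON_type9") channel_params_l()
               else channel_params_t()
  g_par <- numeric(n)
  par <- df$parent
  g_par[-1] <- 1 / (df$r_half[par[-1]] + df$r_half[-1]) # 1/kOhm
  area_cm2 <- df$area * 1e-8
  ve <- numeric(n)
  if (!is.null(field)) {
    pts <- do.call(place_cell,
                   c(list(cell = cell, electrode = field$electrode), placement))
    # field is solved per volt of drive; cable works in mV
    ve <- sample_potential(field, pts) / field$drive * 1000
  }
  chan_code <- ifelse(df$region == "terminal" & !passive,
                      if (channel$type == "T") 1L else 2L, 0L)
  structure(list(
    cell = cell, field = field, channel = channel, placement = placement,
    parent = as.integer(par), g_par = g_par,
    cap = df$capacitance, gleak_abs = cst$g_leak * area_cm2,
    area_cm2 = area_cm2,
    chan = as.integer(chan_code),
    gch_max_abs = channel$gbar * area_cm2 * (chan_code > 0),
    gbar_dens = channel$gbar * (chan_code > 0),
    s_over_v = df$s_over_v,
    ve_profile = ve, v_rest = cst$v_rest, e_leak = cst$e_leak,
    calcium = calcium_params(), passive = passive),
    class = "cbc_system")
}

#' @export
print.cbc_system <- function(x, ...) {
  cat(sprintf("<cbc_system> %s, %d compartments, %s\n",
              x$cell$spec$cell_type, length(x$parent),
              if (x$passive) "passive"
              else sprintf("%s-type channel on %d terminal compartments",
                           x$channel$type, sum(x$chan > 0))))
  if (!is.null(x$field))
    cat(sprintf("  Ve profile %.3g .. %.3g mV per V of drive\n",
                min(x$ve_profile), max(x$ve_profile)))
  invisible(x)
}

#' Linear system operator of the passive cable
#'
#' The matrix `A` (1/ms units) of the passive linearised system
#' `dV/dt = A V + b(t)`, with `A = -C^{-1} (G_leak + L)` where `L` is the
#' axial conductance Laplacian. Exposed for verification against
#' hand-assembled operators.
#'
#' @param system A `cbc_system`.
#' @return Dense n x n matrix.
#' @export
system_matrix <- function(system) {
  n <- length(system$parent)
  L <- matrix(0, n, n)
  for (i in seq_len(n)[-1]) {
    p <- system$parent[i]
    g <- system$g_par[i]
    L[i, i] <- L[i, i] + g
    L[p, p] <- L[p, p] + g
    L[i, p] <- L[i, p] - g
    L[p, i] <- L[p, i] - g
  }
  -diag(1 / system$cap) %*% (diag(system$gleak_abs, n) + L)
}

#' Integrate a system under a stimulus waveform
#'
#' Advances the coupled voltage/gate/calcium equations with an
#' operator-split scheme: exact exponential updates for gates and the
#' calcium pool, backward-Euler solve of the (tree-structured) voltage
#' coupling via Hines elimination. The extracellular drive at a
#' compartment is the unit-drive field sample scaled by the waveform.
#'
#' @param system A `cbc_system`.
#' @param waveform A `cbc_waveform`, or `NULL` for zero drive.
#' @param dt Time step, ms.
#' @param t_end End time, ms (default: waveform duration + 10 ms).
#' @param record_stride Record every k-th step.
#' @param v0 Initial reduced potential per compartment, mV (default 0:
#'   resting).
#' @param i_inj Constant injected current per compartment, uA (testing
#'   hook; default none).
#' @param blowup Abort threshold on `|V|`, mV.
#' @return Object of class `cbc_trace`: `time` (ms) and matrices `vm`
#'   (membrane voltage, mV), `ca` (uM), `ica` (uA/cm^2) of size
#'   time x compartment.
#' @export
advance <- function(system, waveform = NULL, dt = 0.01, t_end = NULL,
                    record_stride = 1L, v0 = NULL, i_inj = NULL,
                    blowup = 1e4) {
  stopifnot(inherits(system, "cbc_system"), dt > 0)
  if (is.null(t_end))
    t_end <- if (is.null(waveform)) 10 else waveform$total + 10
  nt <- ceiling(round(t_end / dt, 6))
  record_stride <- max(1L, as.integer(record_stride))
  nt <- as.integer(ceiling(nt / record_stride) * record_stride)
  tgrid <- seq_len(nt) * dt
  wave <- if (is.null(waveform)) numeric(nt) else waveform_value(waveform, tgrid)
  n <- length(system$parent)
  if (is.null(v0)) v0 <- numeric(n)
  if (is.null(i_inj)) i_inj <- numeric(n)
  stopifnot(length(v0) == n, length(i_inj) == n)
  cst <- cbc_constants()
  vm0 <- v0 + system$v_rest
  m0 <- h0 <- numeric(n)
  act <- system$chan > 0
  if (any(act)) {
    gt <- t_gate_functions(vm0); gl <- l_gate_functions(vm0)
    m0[act] <- ifelse(system$chan[act] == 1L, gt$m_inf[act], gl$m_inf[act])
    h0[act] <- ifelse(system$chan[act] == 1L, gt$h_inf[act], gl$h_inf[act])
  }
  ca0 <- rep(system$calcium$ca_res, n)
  # both channel types share E_K; the mixing weight differs per type
  wmix_t <- if (system$channel$type == "T") system$channel$w else channel_params_t()$w
  wmix_l <- if (system$channel$type == "L") system$channel$w else channel_params_l()$w
  out <- cable_run_cpp(system$parent - 1L, system$g_par, system$cap,
                       system$gleak_abs, system$chan, system$gch_max_abs,
                       system$gbar_dens, system$s_over_v,
                       wmix_t, wmix_l, system$channel$e_k,
                       system$calcium$ca_res, system$calcium$tau,
                       system$calcium$ca_o,
                       system$ve_profile, wave, i_inj,
                       system$v_rest, system$e_leak, dt,
                       record_stride, v0, m0, h0, ca0, blowup)
  if (!out$ok)
    stop(sprintf("numerical blow-up at t = %.3f ms in compartment %d (|V| > %g mV); reduce dt",
                 out$t_fail, out$comp, blowup))
  structure(list(time = c(0, tgrid[seq_len(nt) %% record_stride == 0]),
                 vm = out$vm, ca = out$ca, ica = out$ica,
                 region = system$cell$compartments$region,
                 v_rest = system$v_rest, dt = dt,
                 waveform = waveform,
                 offset = if (is.null(waveform)) 0 else waveform_offset(waveform)),
            class = "cbc_trace")
}

#' @export
print.cbc_trace <- function(x, ...) {
  cat(sprintf("<cbc_trace> %d samples x %d compartments, t = 0..%.3g ms\n",
              nrow(x$vm), ncol(x$vm), max(x$time)))
  cat(sprintf("  Vm range %.1f .. %.1f mV; peak terminal [Ca]_i %.3g uM\n",
              min(x$vm), max(x$vm),
              if (any(x$region == "terminal"))
                max(x$ca[, x$region == "terminal"]) else NA))
  invisible(x)
}

#' @export
plot.cbc_trace <- function(x, what = c("vm", "ca", "ica"),
                           regions = NULL, ...) {
  what <- match.arg(what)
  sel <- if (is.null(regions)) seq_along(x$region)
         else which(x$region %in% regions)
  ylab <- switch(what, vm = "Vm (mV)", ca = "[Ca]_i (uM)",
                 ica = "i_Ca (uA/cm^2)")
  matplot(x$time, x[[what]][, sel, drop = FALSE], type = "l", lty = 1,
          col = c(dendrite = "#D55E00", soma = "#009E73", axon = "#9467bd",
                  terminal = "#E6C229")[x$region[sel]],
          xlab = "time (ms)", ylab = ylab, ...)
  if (what == "vm") abline(h = x$v_rest, lty = 3)
  invisible(x)
}

#' Per-region polarisation summary
#'
#' Maximum depolarisation and hyperpolarisation (Vm - Vrest, mV) over time
#' and compartments within each region.
#'
#' @param trace A `cbc_trace`.
#' @return Data frame with columns `region`, `max_depol`, `max_hyperpol`.
#' @export
region_summary <- function(trace) {
  dv <- sweep(trace$vm, 2, 0) - trace$v_rest
  regs <- unique(trace$region)
  out <- data.frame(
    region = regs,
    max_depol = vapply(regs, function(r)
      max(dv[, trace$region == r, drop = FALSE]), numeric(1)),
    max_hyperpol = vapply(regs, function(r)
      min(dv[, trace$region == r, drop = FALSE]), numeric(1)))
  rownames(out) <- NULL
  out
}

#' Export a trace to CSV
#'
#' Long-format CSV with time, compartment id, region, Vm, [Ca]_i and
#' i_Ca columns.
#'
#' @param trace A `cbc_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  n <- ncol(trace$vm)
  long <- data.frame(
    time = rep(trace$time, n),
    compartment = rep(seq_len(n), each = nrow(trace$vm)),
    region = rep(trace$region, each = nrow(trace$vm)),
    vm = as.vector(trace$vm),
    ca = as.vector(trace$ca),
    ica = as.vector(trace$ica))
  write.table(long, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
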