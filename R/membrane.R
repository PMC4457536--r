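# Active membrane: Hodgkin-Huxley-style T-type and L-type calcium channel
# kinetics, the leak, dynamic intracellular calcium, and the effective
# (K+-blended) calcium reversal potential.

#' T-type calcium channel parameters
#'
#' Low-voltage... transient channel with one activating and one
#' inactivating gate, current density `gbar * m * h * (Vm - VCa_eff)`.
#' The default maximal conductance is 0.954 mS/cm^2. The effective
#' reversal blends the calcium Nernst potential with a potassium
#' equilibrium potential (weight `w`), because at sub-micromolar
#' intracellular calcium most outward current through the open channel is
#' carried by K+.
#'
#' @param gbar Maximal conductance, mS/cm^2.
#' @param w Mixing weight of the Ca Nernst potential (1 = pure Nernst).
#' @param e_k Potassium equilibrium potential, mV.
#' @return Object of class `cbc_channel`.
#' @export
channel_params_t <- function(gbar = 0.954, w = 0.65, e_k = -75) {
  stopifnot(gbar >= 0, w >= 0, w <= 1)
  structure(list(type = "T", gbar = gbar, w = w, e_k = e_k),
            class = "cbc_channel")
}

#' L-type calcium channel parameters
#'
#' High-voltage sustained channel with two activating gates and one slow
#' (292 ms) inactivating gate, current density
#' `gbar * m^2 * h * (Vm - VCa_eff)`; default maximal conductance
#' 1.088 mS/cm^2.
#'
#' @inheritParams channel_params_t
#' @return Object of class `cbc_channel`.
#' @export
channel_params_l <- function(gbar = 1.088, w = 0.67, e_k = -75) {
  stopifnot(gbar >= 0, w >= 0, w <= 1)
  structure(list(type = "L", gbar = gbar, w = w, e_k = e_k),
            class = "cbc_channel")
}

#' Calcium pool parameters
#'
#' Single-pool intracellular calcium: influx proportional to the calcium
#' current density scaled by the compartment's surface-to-volume ratio,
#' relaxation toward the residual level with a fixed time constant,
#' constant extracellular concentration.
#'
#' @param ca_res Residual (resting floor) concentration, uM.
#' @param tau Relaxation time constant, ms.
#' @param ca_o Extracellular concentration, uM (held constant).
#' @return Named list.
#' @export
calcium_params <- function(ca_res = 0.15, tau = 1.5, ca_o = 1800) {
  stopifnot(ca_res > 0, tau > 0, ca_o > 0)
  list(ca_res = ca_res, tau = tau, ca_o = ca_o)
}

#' T-type gating functions
#'
#' Steady states and time constants of the T-type activation (m) and
#' inactivation (h) gates as functions of membrane voltage:
#' `m_inf = 1/(1+exp(-(Vm-37.55)/3.07))`,
#' `tau_m = 1.36 + 21.68/(1+exp((Vm-39.96)/4.11))` ms,
#' `h_inf = 1/(1+exp((Vm-8.97)/8.42))`,
#' `tau_h = 65.82 + 0.0023*exp((Vm-80)/4.78)` ms.
#'
#' @param vm Membrane voltage(s), mV.
#' @return Data frame with columns `m_inf`, `tau_m`, `h_inf`, `tau_h`.
#' @export
t_gate_functions <- function(vm) {
  data.frame(
    m_inf = 1 / (1 + exp(-(vm - 37.55) / 3.07)),
    tau_m = 1.36 + 21.68 / (1 + exp((vm - 39.96) / 4.11)),
    h_inf = 1 / (1 + exp((vm - 8.97) / 8.42)),
    tau_h = 65.82 + 0.0023 * exp((vm - 80) / 4.78))
}

#' L-type gating functions
#'
#' Rate constants of the L-type activation gate,
#' `alpha_m = 0.427 (Vm-63) / (1 - exp(-(Vm-63)/10.5))` (the removable
#' singularity at Vm = 63 mV is evaluated analytically as 0.427 * 10.5)
#' and `beta_m = 0.0406 exp((70-Vm)/12)`, plus the slow inactivation gate
#' `h_inf = 1/(1+exp(Vm/66.4))`, `tau_h = 292` ms. `m_inf` and `tau_m`
#' are derived from the rates.
#'
#' @param vm Membrane voltage(s), mV.
#' @return Data frame with columns `alpha_m`, `beta_m`, `m_inf`, `tau_m`,
#'   `h_inf`, `tau_h`.
#' @export
l_gate_functions <- function(vm) {
  x <- vm - 63
  am <- ifelse(abs(x) < 1e-6, 0.427 * 10.5, 0.427 * x / (1 - exp(-x / 10.5)))
  bm <- 0.0406 * exp((70 - vm) / 12)
  data.frame(alpha_m = am, beta_m = bm,
             m_inf = am / (am + bm), tau_m = 1 / (am + bm),
             h_inf = 1 / (1 + exp(vm / 66.4)), tau_h = 292)
}

#' Calcium Nernst potential at 25 C
#'
#' `E_Ca = (RT/2F) ln([Ca]_o/[Ca]_i)` with RT/2F = 12.85 mV at 298.15 K.
#'
#' @param ca_i Intracellular concentration, uM.
#' @param ca_o Extracellular concentration, uM.
#' @return Potential in mV.
#' @export
nernst_ca <- function(ca_i, ca_o = 1800) {
  if (any(ca_i <= 0) || any(ca_o <= 0)) stop("concentrations must be positive")
  cbc_constants()$rt2f_mV * log(ca_o / ca_i)
}

#' Effective calcium-channel reversal potential
#'
#' Weighted blend `w * E_Ca + (1-w) * E_K` of the dynamic calcium Nernst
#' potential and the potassium equilibrium potential; `w = 1` reduces to
#' the pure Nernst potential, `w = 0` to `E_K`.
#'
#' @param ca_i,ca_o Calcium concentrations, uM.
#' @param w Mixing weight in `[0, 1]`.
#' @param e_k Potassium equilibrium potential, mV.
#' @return Potential in mV.
#' @export
effective_reversal <- function(ca_i, ca_o = 1800, w = 1, e_k = -75) {
  stopifnot(w >= 0, w <= 1)
  if (w == 0) return(rep(e_k, length(ca_i)))
  w * nernst_ca(ca_i, ca_o) + (1 - w) * e_k
}

#' Channel current density
#'
#' `i = gbar * m * h * (Vm - E)` for the T-type channel and
#' `i = gbar * m^2 * h * (Vm - E)` for the L-type channel; positive is
#' outward.
#'
#' @param channel A [channel_params_t()] or [channel_params_l()].
#' @param m,h Gate states in `[0, 1]`.
#' @param vm Membrane voltage, mV.
#' @param e Effective reversal potential, mV (see [effective_reversal()]).
#' @return Current density, uA/cm^2.
#' @export
channel_current <- function(channel, m, h, vm, e) {
  stopifnot(inherits(channel, "cbc_channel"),
            all(m >= 0 & m <= 1), all(h >= 0 & h <= 1))
  open <- if (channel$type == "T") m * h else m^2 * h
  channel$gbar * open * (vm - e)
}

#' Advance the calcium pool by one step
#'
#' Integrates `d[Ca]/dt = -1e4 * (s/v) * i_Ca / (2F) - ([Ca]-[Ca]_res)/tau`
#' (uM, 1/um, uA/cm^2, ms) exactly over `dt` with the current held
#' constant: an exponential relaxation toward the fixed point
#' `[Ca]_res - tau * J`. The residual concentration is a floor: outward
#' current through the channel is carried almost entirely by K+ at these
#' concentrations and cannot deplete the pool below `[Ca]_res`, so steps
#' that would undershoot it are clamped there.
#'
#' @param ca_i Current concentration(s), uM.
#' @param i_ca Calcium current density, uA/cm^2 (positive outward).
#' @param dt Time step, ms.
#' @param s_over_v Surface-to-volume ratio, 1/um.
#' @param params [calcium_params()].
#' @return Updated concentration(s), uM.
#' @export
step_calcium <- function(ca_i, i_ca, dt, s_over_v,
                         params = calcium_params()) {
  if (dt <= 0) stop("dt must be positive")
  J <- 1e4 * s_over_v * i_ca / (2 * cbc_constants()$faraday)
  target <- params$ca_res - params$tau * J
  out <- target + (ca_i - target) * exp(-dt / params$tau)
  pmax(out, params$ca_res)
}

#' Simulated voltage clamp of a single compartment
#'
#' Holds the membrane at `hold` long enough for the gates to settle (they
#' are initialised at their steady state for the holding voltage), then
#' steps to each voltage in `steps` for `t_step` ms and back to the
#' holding voltage for `t_post` ms, recording the channel current density.
#' The calcium pool (and with it the effective reversal) evolves
#' dynamically unless `dynamic_ca = FALSE`.
#'
#' @param channel A `cbc_channel`.
#' @param hold Holding voltage, mV.
#' @param steps Vector of step voltages, mV.
#' @param t_step Step duration, ms.
#' @param t_pre,t_post Pre- and post-step time at holding voltage, ms.
#' @param dt Time step, ms.
#' @param s_over_v Surface-to-volume ratio of the clamped compartment, 1/um.
#' @param calcium [calcium_params()].
#' @param dynamic_ca Evolve intracellular calcium during the clamp.
#' @return Object of class `cbc_clamp`: `time` (ms) and one column per
#'   step voltage in the matrices `i` (uA/cm^2), `m`, `h`, `ca` (uM),
#'   plus the command matrix `vm`.
#' @export
run_voltage_clamp <- function(channel, hold = -80, steps = seq(-55, 45, by = 25),
                              t_step = 300, t_pre = 20, t_post = 100,
                              dt = 0.01, s_over_v = 4,
                              calcium = calcium_params(),
                              dynamic_ca = TRUE) {
  stopifnot(inherits(channel, "cbc_channel"))
  if (length(steps) == 0) stop("empty clamp protocol")
  nt <- round((t_pre + t_step + t_post) / dt) + 1
  tgrid <- (seq_len(nt) - 1) * dt
  type <- if (channel$type == "T") 1L else 2L
  g0 <- if (type == 1L) t_gate_functions(hold) else l_gate_functions(hold)
  res <- lapply(steps, function(vs) {
    vm <- ifelse(tgrid >= t_pre & tgrid < t_pre + t_step, vs, hold)
    clamp_run_cpp(type, channel$gbar, channel$w, channel$e_k, vm, dt,
                  s_over_v, calcium$ca_res, calcium$tau, calcium$ca_o,
                  dynamic_ca, 1L, g0$m_inf, g0$h_inf, calcium$ca_res)
  })
  structure(list(time = tgrid,
                 vm = vapply(seq_along(steps), function(k)
                   ifelse(tgrid >= t_pre & tgrid < t_pre + t_step,
                          steps[k], hold), numeric(nt)),
                 i = vapply(res, function(r) r$i, numeric(nt)),
                 m = vapply(res, function(r) r$m, numeric(nt)),
                 h = vapply(res, function(r) r$h, numeric(nt)),
                 ca = vapply(res, function(r) r$ca, numeric(nt)),
                 hold = hold, steps = steps, channel = channel,
                 t_pre = t_pre, t_step = t_step),
            class = "cbc_clamp")
}

#' @export
print.cbc_clamp <- function(x, ...) {
  cat(sprintf("<cbc_clamp> %s-type, hold %g mV, steps: %s mV\n",
              x$channel$type, x$hold, paste(x$steps, collapse = ", ")))
  pk <- apply(x$i, 2, function(col) col[which.max(abs(col))])
  cat("  extreme current densities (uA/cm^2):",
      paste(sprintf("%.2f", pk), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.cbc_clamp <- function(x, ...) {
  matplot(x$time, x$i, type = "l", lty = 1,
          xlab = "time (ms)", ylab = "current density (uA/cm^2)",
          main = sprintf("%s-type voltage clamp", x$channel$type), ...)
  legend("bottomright", legend = sprintf("%g mV", x$steps),
         col = seq_along(x$steps), lty = 1, cex = 0.8)
  invisible(x)
}
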