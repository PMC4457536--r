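test_that("T-type gating functions hit their closed-form anchors", {
  g <- t_gate_functions(37.55)
  expect_equal(g$m_inf, 0.5, tolerance = 1e-12)
  g <- t_gate_functions(8.97)
  expect_equal(g$h_inf, 0.5, tolerance = 1e-12)
  # at the tau_m midpoint voltage the exponential is 1: 1.36 + 21.68/2
  g <- t_gate_functions(39.96)
  expect_equal(g$tau_m, 12.20, tolerance = 1e-12)
  # time constants positive over a wide voltage range
  g <- t_gate_functions(seq(-150, 150, by = 1))
  expect_true(all(g$tau_m > 0 & g$tau_h > 0))
  expect_true(all(g$m_inf >= 0 & g$m_inf <= 1 & g$h_inf >= 0 & g$h_inf <= 1))
})

test_that("L-type rates handle the removable singularity analytically", {
  g <- l_gate_functions(63)
  expect_equal(g$alpha_m, 0.427 * 10.5, tolerance = 1e-12)
  # continuous through the singularity
  eps <- l_gate_functions(c(63 - 1e-7, 63 + 1e-7))
  expect_equal(eps$alpha_m, rep(0.427 * 10.5, 2), tolerance = 1e-5)
  expect_equal(l_gate_functions(0)$h_inf, 0.5, tolerance = 1e-12)
  expect_equal(l_gate_functions(-120)$tau_h, 292)
  g <- l_gate_functions(seq(-150, 150, by = 1))
  expect_true(all(g$alpha_m >= 0 & g$beta_m >= 0))
})

test_that("channel current follows the conductance law", {
  tch <- channel_params_t(); lch <- channel_params_l()
  expect_equal(channel_current(tch, 0, 1, 50, -20), 0)
  expect_equal(channel_current(tch, 0.5, 0.5, -20, -20), 0) # at reversal
  # gbar x driving force; mS/cm2 x mV = uA/cm2
  expect_equal(channel_current(tch, 1, 1, -100 + 10, 10), -95.4,
               tolerance = 1e-12)
  # L-type uses m^2
  expect_equal(channel_current(lch, 0.5, 1, 0, -50),
               1.088 * 0.25 * 50, tolerance = 1e-12)
  expect_error(channel_current(tch, 1.5, 1, 0, 0))
})

test_that("effective reversal blends Nernst and E_K", {
  rt2f <- 1000 * 8.314462618 * 298.15 / (2 * 96489)
  expect_equal(effective_reversal(1800, 1800, w = 1), 0, tolerance = 1e-12)
  expect_equal(effective_reversal(0.15, 1800, w = 1),
               rt2f * log(12000), tolerance = 1e-12)
  expect_equal(effective_reversal(0.15, 1800, w = 1), 120.65,
               tolerance = 1e-4)
  expect_equal(effective_reversal(0.15, 1800, w = 0, e_k = -75), -75)
  # continuous and monotone in ca_i
  e <- effective_reversal(c(0.15, 0.3, 1, 3), w = 0.65)
  expect_true(all(diff(e) < 0))
  expect_error(effective_reversal(-1, 1800, w = 1), "positive")
})

test_that("calcium pool relaxes exactly per the closed form", {
  cal <- calcium_params()
  # fixed point at rest
  expect_equal(step_calcium(0.15, 0, 0.1, 4), 0.15, tolerance = 1e-12)
  # zero current: exponential decay toward the residual, tau = 1.5 ms
  ca <- 0.95
  for (k in 1:100) ca <- step_calcium(ca, 0, 0.03, 4)
  expect_equal(ca, 0.15 + 0.8 * exp(-3 / 1.5), tolerance = 1e-9)
  # constant inward current: analytic steady state
  i_in <- -20 # uA/cm2
  sv <- 4
  ca <- 0.15
  for (k in 1:4000) ca <- step_calcium(ca, i_in, 0.01, sv)
  target <- 0.15 + 1.5 * 1e4 * sv * 20 / (2 * 96489)
  expect_equal(ca, target, tolerance = 1e-3 * target)
  # residual level is a floor under outward current
  expect_equal(step_calcium(0.15, 100, 1, 4), 0.15)
  expect_error(step_calcium(0.15, 0, -1, 4), "positive")
})

test_that("gate integration matches closed-form exponential relaxation", {
  # fixed command voltage: m(t) = m_inf - (m_inf - m0) exp(-t/tau_m)
  ch <- channel_params_t()
  cl <- run_voltage_clamp(ch, hold = -80, steps = 10, t_pre = 0,
                          t_step = 60, t_post = 0, dt = 0.01,
                          dynamic_ca = FALSE)
  g0 <- t_gate_functions(-80); g1 <- t_gate_functions(10)
  t <- cl$time
  idx <- which(t > 0 & t < 60) # inside the constant-voltage window
  m_exact <- g1$m_inf + (g0$m_inf - g1$m_inf) * exp(-t / g1$tau_m)
  h_exact <- g1$h_inf + (g0$h_inf - g1$h_inf) * exp(-t / g1$tau_h)
  expect_lt(max(abs(cl$m[idx, 1] - m_exact[idx]) / pmax(m_exact[idx], 1e-12)),
            1e-6)
  expect_lt(max(abs(cl$h[idx, 1] - h_exact[idx]) / h_exact[idx]), 1e-6)
  # gates bounded in [0, 1] under an extreme voltage excursion
  cl2 <- run_voltage_clamp(ch, hold = -80, steps = 400, t_step = 50,
                           t_post = 50)
  expect_true(all(cl2$m >= 0 & cl2$m <= 1 & cl2$h >= 0 & cl2$h <= 1))
})

test_that("T-type clamp currents are transient, L-type sustained", {
  # no step change: flat trace
  flat <- run_voltage_clamp(channel_params_t(), hold = -80, steps = -80,
                            t_step = 50)
  expect_lt(diff(range(flat$i)), 1e-9)

  # T-type, hold -80, step +45: inward current rises then decays toward a
  # small steady level (inactivation)
  tc <- run_voltage_clamp(channel_params_t(), hold = -80, steps = 45,
                          t_pre = 5, t_step = 300, t_post = 0,
                          dynamic_ca = FALSE)
  instep <- tc$time > 5 & tc$time < 305
  i <- tc$i[instep, 1]
  expect_lt(min(i), 0) # inward
  ipk <- which.min(i)
  expect_gt(ipk, 10)               # rises first
  expect_lt(ipk, sum(instep) / 2)  # peaks in the first half
  expect_lt(abs(i[length(i)]), 0.05 * abs(min(i))) # decays away
  # all steps up to +45 stay inward (reversal above the step range)
  fam <- run_voltage_clamp(channel_params_t(), hold = -80,
                           steps = seq(-55, 45, by = 25), t_step = 300)
  expect_true(all(apply(fam$i, 2, min) <= 0))

  # L-type family: sustained currents, peak magnitude non-monotone in the
  # step voltage (activation/driving-force trade-off)
  lf <- run_voltage_clamp(channel_params_l(), hold = -70,
                          steps = c(-45, -20, 5, 30, 55), t_pre = 5,
                          t_step = 300, t_post = 0, dynamic_ca = FALSE)
  pk <- apply(abs(lf$i), 2, max)
  expect_gt(pk[4], pk[3]) # grows toward +30
  expect_gt(pk[4], pk[5]) # falls again at +55: non-monotone
  # sustained: more than half the peak remains near the end of the +30 step
  iend <- abs(lf$i[max(which(lf$time < 305)) - 5, 4])
  expect_gt(iend, 0.5 * pk[4])
  expect_error(run_voltage_clamp(channel_params_t(), steps = numeric(0)),
               "empty")
})
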