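test_that("the two-compartment passive operator matches a hand assembly", {
  cell <- read_swc(two_comp_swc())
  sys <- assemble(cell, field = NULL, passive = TRUE)
  A <- system_matrix(sys)
  # hand assembly: soma sphere d = 11 um, cylinder 10 x 1.2 um
  cst <- cbc_constants()
  r_s <- cst$rho_a * (11 / 2 * 1e-4) / (pi * (5.5e-4)^2) / 1000 # kOhm
  r_c <- cst$rho_a * (10 / 2 * 1e-4) / (pi * (0.6e-4)^2) / 1000
  g <- 1 / (r_s + r_c)                      # 1/kOhm
  a_s <- 4 * pi * 5.5^2 * 1e-8              # cm^2
  a_c <- pi * 1.2 * 10 * 1e-8
  C_s <- cst$cm * a_s; C_c <- cst$cm * a_c  # uF
  gl_s <- cst$g_leak * a_s; gl_c <- cst$g_leak * a_c
  A_hand <- rbind(c(-(gl_s + g) / C_s, g / C_s),
                  c(g / C_c, -(gl_c + g) / C_c))
  expect_equal(A, A_hand, tolerance = 1e-10)
  # assembling twice is deterministic
  expect_equal(assemble(cell, NULL, passive = TRUE)[c("g_par", "cap")],
               sys[c("g_par", "cap")], tolerance = 1e-15)
})

test_that("branch points couple one term per neighbour", {
  sys <- assemble(on_cell(), NULL, passive = TRUE)
  A <- system_matrix(sys)
  # the soma row has one off-diagonal per attached branch:
  # 6 dendritic branches + the axon
  expect_identical(sum(A[1, -1] != 0), 7L)
  # a mid-chain axon compartment has exactly 2 neighbours
  ax <- which(sys$cell$compartments$region == "axon")[5]
  expect_identical(sum(A[ax, -ax] != 0), 2L)
  # axial coupling is reciprocal: conductance-symmetric rows
  Gsym <- A * sys$cap # row-scale by C: -(G+L) is symmetric
  expect_equal(Gsym, t(Gsym), tolerance = 1e-10)
})

test_that("resting state is a fixed point and uniform Ve does not polarise", {
  sys <- assemble(off_cell(), NULL, passive = TRUE)
  tr <- advance(sys, NULL, dt = 0.01, t_end = 5)
  expect_lt(max(abs(tr$vm - (-53.08))), 1e-9)
  # spatially uniform extracellular potential: driving terms are Ve
  # differences, so nothing happens regardless of amplitude
  sys$ve_profile <- rep(250, length(sys$parent))
  tr2 <- advance(sys, monophasic(2, 1, "cathodic"), dt = 0.01, t_end = 3)
  expect_lt(max(abs(tr2$vm - (-53.08))), 1e-9)
})

test_that("a single passive compartment charges with tau = cm/g_leak", {
  cell <- read_swc(single_soma_swc())
  sys <- assemble(cell, NULL, passive = TRUE)
  # constant injected current: V(t) = V_inf (1 - exp(-t/tau)), tau ~ 26.4 ms
  i0 <- 1e-4 # uA
  tr <- advance(sys, NULL, dt = 0.01, t_end = 120, i_inj = i0)
  tau <- cbc_constants()$cm / cbc_constants()$g_leak
  v_inf <- i0 / sys$gleak_abs[1]
  v <- tr$vm[, 1] - (-53.08)
  t <- tr$time
  expect_equal(tau, 26.38, tolerance = 1e-3)
  expect_lt(max(abs(v - v_inf * (1 - exp(-t / tau)))) / v_inf, 1e-3)
})

test_that("passive responses are linear in the waveform amplitude", {
  f <- std_field()
  sys <- assemble(on_cell(), f, passive = TRUE)
  tr1 <- advance(sys, monophasic(1, 1, "cathodic"), dt = 0.01, t_end = 4)
  tr2 <- advance(sys, monophasic(2, 1, "cathodic"), dt = 0.01, t_end = 4)
  dv1 <- tr1$vm - (-53.08); dv2 <- tr2$vm - (-53.08)
  expect_lt(max(abs(dv2 - 2 * dv1)), 1e-8 * max(abs(dv2)))
})

test_that("halving dt converges at first order or better", {
  f <- std_field()
  sys <- assemble(on_cell(), f, passive = FALSE)
  w <- monophasic(1, 1, "cathodic")
  term <- which(on_cell()$compartments$region == "terminal")
  run <- function(dt, stride) advance(sys, w, dt = dt, t_end = 8,
                                      record_stride = stride)$vm[, term]
  v1 <- run(0.04, 1L); v2 <- run(0.02, 2L); v3 <- run(0.01, 4L)
  err12 <- max(abs(v2 - v1))
  err23 <- max(abs(v3 - v2))
  expect_lt(err23, err12)
  expect_lt(err23, 0.6 * err12) # at least ~first-order reduction
})

test_that("the standard cathodic pulse polarises regions with the right signs", {
  f <- std_field()
  tr <- advance(assemble(on_cell(), f, passive = TRUE),
                monophasic(1, 1, "cathodic"), dt = 0.01, t_end = 4)
  rs <- region_summary(tr)
  # dendrites (facing the electrode) hyperpolarise, terminals depolarise
  expect_lt(rs$max_hyperpol[rs$region == "dendrite"], -50)
  expect_gt(rs$max_depol[rs$region == "terminal"], 50)
  expect_lt(rs$max_depol[rs$region == "dendrite"], 5)
  # anodic pulse mirrors the pattern
  tra <- advance(assemble(on_cell(), f, passive = TRUE),
                 monophasic(1, 1, "anodic"), dt = 0.01, t_end = 4)
  rsa <- region_summary(tra)
  expect_gt(rsa$max_depol[rsa$region == "dendrite"], 50)
  expect_lt(rsa$max_hyperpol[rsa$region == "terminal"], -50)
})

test_that("blow-up aborts with a diagnostic", {
  sys <- assemble(on_cell(), std_field(), passive = TRUE)
  expect_error(advance(sys, monophasic(1e7, 1, "cathodic"), dt = 0.01,
                       t_end = 2, blowup = 1e3), "blow-up")
})

test_that("traces export to CSV", {
  sys <- assemble(read_swc(two_comp_swc()), NULL, passive = TRUE)
  tr <- advance(sys, NULL, t_end = 1)
  path <- tempfile(fileext = ".csv")
  write_trace_csv(tr, path)
  back <- read.csv(path)
  expect_identical(nrow(back), nrow(tr$vm) * 2L)
  expect_equal(back$vm[1], tr$vm[1, 1])
})
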