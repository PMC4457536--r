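test_that("a 0 V pulse changes nothing", {
  r <- run_standard(on_cell(), std_field(), monophasic(0, 1, "cathodic"),
                    t_end = 5)
  expect_lt(abs(r$summary$terminal_depol), 1e-9)
  expect_lt(abs(r$summary$dendrite_hyperpol), 1e-9)
  expect_equal(r$summary$peak_ca, calcium_params()$ca_res, tolerance = 1e-9)
  expect_equal(r$summary$decay_ms, 0)
})

test_that("passive ON terminals depolarise more than OFF under the standard pulse", {
  ron <- run_standard(on_cell(), std_field(), monophasic(1, 1, "cathodic"),
                      active = FALSE, t_end = 5)
  roff <- run_standard(off_cell(), std_field(), monophasic(1, 1, "cathodic"),
                       active = FALSE, t_end = 5)
  expect_gt(ron$summary$terminal_depol, roff$summary$terminal_depol)
  # both dendritic trees hyperpolarise strongly
  expect_lt(ron$summary$dendrite_hyperpol, -100)
  expect_lt(roff$summary$dendrite_hyperpol, -100)
})

test_that("the active OFF cell evokes more sustained, larger calcium", {
  ron <- run_standard(on_cell(), std_field(), monophasic(1, 0.5, "cathodic"),
                      t_end = 40)
  roff <- run_standard(off_cell(), std_field(), monophasic(1, 0.5, "cathodic"),
                       t_end = 260)
  expect_gt(roff$summary$peak_ca, ron$summary$peak_ca)
  expect_gt(roff$summary$decay_ms, ron$summary$decay_ms)
})

test_that("ON calcium saturates between 1 V and 2 V but not at 0.5 V", {
  pk <- vapply(c(0.5, 1, 2), function(A)
    run_standard(on_cell(), std_field(), monophasic(A, 0.5, "cathodic"),
                 t_end = 30)$summary$peak_ca, numeric(1))
  exc <- pk - calcium_params()$ca_res
  expect_lt(abs(exc[3] - exc[2]) / exc[2], 0.10) # 1 V vs 2 V within 10%
  expect_lt(exc[1], 0.75 * exc[2])               # 0.5 V materially lower
})

test_that("axon-length sweep weakens polarisation monotonically", {
  sw <- axon_length_sweep(on_cell(), std_field(), t_end = 5)
  expect_identical(nrow(sw$table), 9L)
  expect_equal(sw$table$factor, seq(1, 0.2, by = -0.1))
  expect_true(all(diff(sw$table$terminal_depol) < 0)) # shrinks with factor
  expect_true(all(diff(sw$table$dendrite_hyperpol) > 0))
  # the factor-1 row reproduces the standard run
  std <- run_standard(on_cell(), std_field(), monophasic(1, 1, "cathodic"),
                      active = FALSE, t_end = 5)
  expect_equal(sw$table$terminal_depol[1], std$summary$terminal_depol,
               tolerance = 1e-10)
})

test_that("position maps have the configured shape and a degenerate map matches run_standard", {
  pm1 <- position_map(on_cell(), std_field(), x_range = c(0, 0),
                      z_range = c(0, 0), t_end = 15)
  expect_identical(dim(pm1$peak_ca), c(1L, 1L))
  std <- run_standard(on_cell(), std_field(), monophasic(1, 1, "cathodic"),
                      t_end = 15)
  expect_equal(pm1$peak_ca[1, 1], std$summary$peak_ca, tolerance = 1e-10)
  pm <- position_map(off_cell(), std_field(), x_range = c(-4, 4),
                     z_range = c(0, 4), step = 4, t_end = 15)
  expect_identical(dim(pm$peak_ca), c(3L, 2L))
  expect_identical(length(pm$peak_ca), 6L)
})

test_that("OFF position maps vary far more than ON maps", {
  rng <- function(cell) {
    pm <- position_map(cell, std_field(), x_range = c(-8, 8),
                       z_range = c(0, 8), step = 4, t_end = 15)
    diff(range(pm$peak_ca)) / min(pm$peak_ca)
  }
  expect_gt(rng(off_cell()), 2 * rng(on_cell()))
})

test_that("calcium decay measurement handles trivial and censored traces", {
  # never leaves baseline
  r0 <- run_standard(on_cell(), std_field(), monophasic(0, 1), t_end = 5)
  d0 <- ca_decay_time(r0$trace)
  expect_equal(d0$decay_ms, 0)
  expect_false(d0$censored)
  # OFF cell cut short: still elevated at the end of the trace
  roff <- run_standard(off_cell(), std_field(), monophasic(1, 0.5),
                       t_end = 5)
  expect_true(ca_decay_time(roff$trace)$censored)
})

test_that("opposite biphasic phase orders favour opposite cells", {
  peak <- function(cell, ord, t_end)
    run_standard(cell, std_field(), biphasic(1, 1, 50, ord),
                 t_end = t_end)$summary$peak_ca
  on_cf <- peak(on_cell(), "cathodic_first", 30)
  on_af <- peak(on_cell(), "anodic_first", 30)
  off_cf <- peak(off_cell(), "cathodic_first", 30)
  off_af <- peak(off_cell(), "anodic_first", 30)
  # each cell has a clear preference, and the preferences are opposite:
  # the phase order that maximises ON calcium is not the one that
  # maximises OFF calcium
  expect_gt(abs(on_cf - on_af) / max(on_cf, on_af), 0.05)
  expect_gt(abs(off_cf - off_af) / max(off_cf, off_af), 0.05)
  expect_true((on_cf > on_af) != (off_cf > off_af))
})

test_that("bursts accumulate calcium in the OFF cell", {
  b <- burst(monophasic(1, 0.5, "cathodic"), 5, 0.5)
  single <- run_standard(off_cell(), std_field(), monophasic(1, 0.5),
                         t_end = 30)$summary$peak_ca
  rep5 <- run_standard(off_cell(), std_field(), b, t_end = 30)$summary$peak_ca
  expect_gt(rep5, 1.2 * single)
  # ON cell: burst peak never below the single-pulse peak
  s_on <- run_standard(on_cell(), std_field(), monophasic(1, 0.5),
                       t_end = 30)$summary$peak_ca
  b_on <- run_standard(on_cell(), std_field(), b, t_end = 30)$summary$peak_ca
  expect_gte(b_on, 0.99 * s_on)
})

test_that("identical channel equipment nearly equalises the two cells", {
  cells <- list(on_cell(), off_cell())
  sw1 <- channel_swap(cells, std_field(), channel_params_l(),
                      monophasic(1, 0.5, "cathodic"), t_end = 30)
  exc1 <- sw1$peak_ca - calcium_params()$ca_res
  # with the same channel the 1 V responses agree within a factor of 2 ...
  expect_lt(max(exc1) / min(exc1), 2)
  # ... whereas the native channel complements differ many-fold
  nat <- vapply(cells, function(cl)
    run_standard(cl, std_field(), monophasic(1, 0.5, "cathodic"),
                 t_end = 30)$summary$peak_ca, numeric(1)) -
    calcium_params()$ca_res
  expect_gt(max(nat) / min(nat), 2 * max(exc1) / min(exc1))
  # weaker 0.5 V pulse: the more depolarised ON cell wins
  sw05 <- channel_swap(cells, std_field(), channel_params_l(),
                       monophasic(0.5, 0.5, "cathodic"), t_end = 30)
  expect_gt(sw05$peak_ca[1], sw05$peak_ca[2])
  # swapping the cell order permutes rows only
  swr <- channel_swap(rev(cells), std_field(), channel_params_l(),
                      monophasic(1, 0.5, "cathodic"), t_end = 30)
  expect_equal(swr$peak_ca, rev(sw1$peak_ca), tolerance = 1e-12)
})

test_that("frequency response normalises to its own maximum", {
  fr <- frequency_response(channel_params_t(), freqs = 5)
  expect_equal(fr$table$normalized, 1)
  expect_equal(fr$argmax_Hz, 5)
  fr2 <- frequency_response(channel_params_l(), freqs = c(2, 20, 200))
  expect_equal(max(fr2$table$normalized), 1)
  expect_true(all(fr2$table$normalized >= 0 & fr2$table$normalized <= 1))
})
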