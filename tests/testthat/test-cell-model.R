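test_that("drug block table and validation follow the dose-response convention", {
  expect_equal(drug_block(0)$block_factor, 1)
  expect_equal(drug_block(0.1)$block_factor, 0.45)
  expect_equal(drug_block(1)$block_factor, 0.12)
  expect_equal(drug_block(block_factor = 0.5)$block_factor, 0.5)
  expect_error(drug_block(0.3), "supply `block_factor`")
  expect_error(drug_block(block_factor = 0), "\\(0, 1\\]")
  expect_error(drug_block(block_factor = 1.2), "\\(0, 1\\]")
})

test_that("channel count and single-channel block enter only through their product", {
  expect_equal(ical_scaling(1, drug_block(0)), 1)
  expect_equal(ical_scaling(10, drug_block(block_factor = 0.1)), 1)
  expect_equal(ical_scaling(1, drug_block(1)), 0.12)
  expect_error(ical_scaling(0), "positive")
  m <- test_model()
  st <- limit_cycle_init(m)
  d1 <- cell_derivatives(m, st, n = 10, drug = drug_block(block_factor = 0.1))
  d2 <- cell_derivatives(m, st, n = 1, drug = drug_block(0))
  expect_equal(d1, d2, tolerance = 1e-12)
  ## and at the trace level
  tr1 <- run_fixed_n(m, n = 10, drug = drug_block(block_factor = 0.1),
                     duration_ms = 10000, initial_state = st)
  tr2 <- run_fixed_n(m, n = 1, drug = drug_block(0), duration_ms = 10000,
                     initial_state = st)
  expect_lt(max(abs(tr1$V_mV - tr2$V_mV)), 1e-6)
})

test_that("compiled solver kernel agrees with the R reference derivatives", {
  m <- test_model()
  ## integrate the R right-hand side and the compiled one over the same
  ## window and compare the trajectories
  st <- limit_cycle_init(m)
  r_rhs <- function(t, y, p) list(unname(cell_derivatives(m, y)))
  times <- seq(0, 4000, by = 2)
  outR <- deSolve::ode(st, times, r_rhs, NULL, method = "bdf",
                       rtol = 1e-8, atol = 1e-10)
  outC <- chanreg:::hpcm_integrate(m, 1, drug_block(0), 4000, st,
                                   rtol = 1e-8,
                                   atol = rep(1e-10, 9))
  expect_lt(max(abs(outR[, "V"] - outC[, "V"])), 0.05)
  expect_lt(max(abs(outR[, "c"] - outC[, "c"])), 1e-6)
  ## pointwise agreement of the two implementations at assorted states
  set.seed(21)
  for (i in 1:5) {
    y <- stats::setNames(as.numeric(st) * exp(rnorm(9, 0, 0.05)),
                         m$state_names)
    dR <- cell_derivatives(m, y)
    p <- chanreg:::hpcm_parms_vector(m)
    outs <- deSolve::ode(y, c(0, 0.5), func = m$derivfunc, parms = p,
                         dllname = m$dll, initfunc = m$initfunc,
                         method = "euler")
    dC <- (outs[2, -1] - y) / 0.5
    expect_equal(as.numeric(dC), as.numeric(dR), tolerance = 1e-6)
  }
})

test_that("the default model beats spontaneously with bounded positive calcium", {
  m <- test_model()
  tr <- run_fixed_n(m, duration_ms = 70000)
  tail10 <- tr[tr$time_ms >= 60000, ]
  ups <- detect_beats(tail10)
  expect_gte(length(ups), 3)
  expect_true(all(tr$c_mM > 0))
  expect_true(all(tr$c_mM < 0.01))
  ## amplitude and voltage range are physiological for hiPSC-CMs
  expect_gt(max(tail10$V_mV) - min(tail10$V_mV), 80)
  expect_lt(min(tail10$V_mV), -60)
})

test_that("reducing CaL density monotonically reduces cycle-averaged calcium", {
  m <- test_model()
  scales <- c(0.8, 0.9, 1.0, 1.1, 1.2)
  cbars <- vapply(scales, function(s) {
    r <- perturb_and_measure(m, "CaL", scale = s, settle_ms = 2e5)
    r$cbar_mM
  }, numeric(1))
  expect_true(all(diff(cbars) > 0))
})

test_that("equilibrated initialization is deterministic and phase-aligned", {
  m <- test_model()
  st1 <- limit_cycle_init(m, equilibration_ms = 60000)
  st2 <- limit_cycle_init(m, equilibration_ms = 60000)
  expect_identical(st1, st2)
  expect_false(attr(st1, "quiescent"))
  ## upstroke-aligned: the voltage is mid-upstroke, far from the MDP
  expect_gt(st1[["V"]], -40)
  ## a quiescent configuration returns a flagged state, not an error
  mq <- cell_model(scale_factors = c(CaL = 0, Na = 0, f = 0))
  stq <- limit_cycle_init(mq, equilibration_ms = 30000)
  expect_true(attr(stq, "quiescent"))
})

test_that("the calcium target is a stable cycle average of the default model", {
  m <- test_model()
  cstar <- test_cstar()
  expect_gt(cstar, 5e-5)
  expect_lt(cstar, 1e-3)
  ## re-simulating and re-averaging recovers it within 1%
  st <- limit_cycle_init(m)
  out <- chanreg:::hpcm_integrate(m, 1, drug_block(0), 20000, st)
  tr <- as_trace(tibble::tibble(time_ms = out[, "time"], V_mV = out[, "V"],
                                c_mM = out[, "c"]))
  re <- chanreg:::cycle_average_calcium(tr)
  expect_lt(abs(as.numeric(re) - cstar) / cstar, 0.01)
  ## averaging over 1 vs 3 complete cycles differs by < 0.5%
  ups <- detect_beats(tr)
  one <- tr[tr$time_ms >= ups[length(ups) - 1] & tr$time_ms <= ups[length(ups)], ]
  three <- tr[tr$time_ms >= ups[length(ups) - 3] & tr$time_ms <= ups[length(ups)], ]
  a1 <- chanreg:::trapz_mean(one$time_ms, one$c_mM)
  a3 <- chanreg:::trapz_mean(three$time_ms, three$c_mM)
  expect_lt(abs(a1 - a3) / a3, 0.005)
  ## halving solver tolerances moves the estimate by < 0.5%
  tight <- as.numeric(compute_target_calcium(m, rtol = 5e-7))
  expect_lt(abs(tight - cstar) / cstar, 0.005)
})

test_that("cell model constructor validates protein types and parameters", {
  expect_error(cell_model("nosuch"), "unknown cell model")
  expect_error(cell_model(scale_factors = c(Cav12 = 1.2)), "unknown protein")
  expect_error(cell_model(pars = list(gXYZ = 1)), "unknown model parameter")
  m <- cell_model(scale_factors = c(Kr = 1.3))
  expect_equal(m$pars$scale[["Kr"]], 1.3)
  expect_true(all(c("CaL", "Na", "f", "Kr", "K1", "SERCA") %in%
                    protein_types(m)))
  ## non-finite states are rejected with the component named
  expect_error(cell_derivatives(m, replace(m$state0, 3, NaN)), "hNa")
})
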