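test_that("the default state is a fixed point of the coupled system", {
  m <- test_model()
  sim <- simulate_coupled(m, regulation = "two_ode", params = test_params(),
                          drug = drug_block(0), t_end_ms = 6 * 3.6e6,
                          method = "averaged")
  expect_true(all(abs(tidy(sim)$n - 1) < 0.02))
  expect_true(all(abs(tidy(sim)$m - 1) < 0.02))
})

test_that("averaged accelerator matches direct integration within 2%", {
  m <- test_model()
  ## compressed mRNA time scale keeps direct integration affordable while
  ## respecting the slow-fast precondition
  pc <- test_params(tau_m_mM_ms = 80)
  drug <- drug_block(block_factor = 0.1)
  dir <- simulate_coupled(m, "two_ode", params = pc, drug = drug,
                          t_end_ms = 250e3, method = "direct")
  avg <- simulate_coupled(m, "two_ode", params = pc, drug = drug,
                          t_end_ms = 250e3, method = "averaged",
                          relax_ms = 3000, window_ms = 6000,
                          dn_target = 0.04, dt_slow_min_ms = 5000)
  a <- tidy(avg); d <- tidy(dir)
  n_dir <- stats::approx(d$time_ms, d$n, xout = a$time_ms)$y
  ok <- !is.na(n_dir)
  expect_lt(max(abs(a$n[ok] - n_dir[ok]) / n_dir[ok]), 0.02)
})

test_that("the averaged method refuses to run outside its slow-fast regime", {
  m <- test_model()
  fast <- test_params(tau_m_mM_ms = 4)
  expect_error(
    simulate_coupled(m, "two_ode", params = fast,
                     drug = drug_block(block_factor = 0.1),
                     t_end_ms = 60e3, method = "averaged"),
    "slow-fast precondition.*direct"
  )
})

test_that("scaling the mRNA time constant rescales the slow time axis", {
  m <- test_model()
  drug <- drug_block(0.1)
  simA <- simulate_coupled(m, "two_ode", params = test_params(),
                           drug = drug, t_end_ms = 8 * 3.6e6,
                           method = "averaged")
  s <- 4
  simB <- simulate_coupled(m, "two_ode",
                           params = test_params(tau_m_mM_ms = 400 / s),
                           drug = drug, t_end_ms = 8 * 3.6e6 / s,
                           method = "averaged")
  a <- tidy(simA); b <- tidy(simB)
  nB <- stats::approx(b$time_ms * s, b$n, xout = a$time_ms)$y
  ok <- !is.na(nB) & a$n > 1.05
  expect_gt(sum(ok), 5)
  expect_lt(max(abs(a$n[ok] - nB[ok]) / a$n[ok]), 0.03)
  ## equilibria unchanged by compression
  expect_lt(abs(glance(simA)$n_final - glance(simB)$n_final) /
              glance(simA)$n_final, 0.02)
})

test_that("mRNA/protein deviation stays inside the Gronwall envelope", {
  m <- test_model()
  pc <- test_params(tau_m_mM_ms = 80)
  dir <- simulate_coupled(m, "two_ode", params = pc,
                          drug = drug_block(block_factor = 0.45),
                          t_end_ms = 150e3, method = "direct")
  df <- tidy(dir)
  S <- dir$provenance$cdev_sup_mM
  env <- gronwall_bound(df$time_ms, p0 = abs(df$m[1] - df$n[1]),
                        cdev_sup = S, params = pc)
  expect_true(all(abs(df$m - df$n) <= env + 1e-9))
  ## and the asymptotic bound is respected on the trajectory tail
  tail_dev <- abs(df$m - df$n)[df$time_ms > 50e3]
  expect_true(all(tail_dev <=
                    (pc$tau_n_traffic_ms / pc$tau_m_mM_ms) * S + 1e-9))
})

test_that("bounded trajectories are confined to the expression band", {
  m <- test_model()
  sim <- simulate_coupled(m, "bounded", params = test_params(),
                          drug = drug_block(block_factor = 0.1),
                          t_end_ms = 24 * 3.6e6, method = "averaged")
  n <- tidy(sim)$n
  expect_true(all(n <= 3 + 0.05))
  expect_true(all(n >= 0.1 - 0.05))
})

test_that("a quiescent cell is averaged over the window without error", {
  mq <- cell_model(scale_factors = c(CaL = 0, Na = 0, f = 0))
  stq <- limit_cycle_init(mq, equilibration_ms = 30000)
  expect_true(attr(stq, "quiescent"))
  p <- test_params()
  sim <- simulate_coupled(mq, "bounded", params = p,
                          drug = drug_block(block_factor = 0.5),
                          t_end_ms = 2 * 3.6e6, method = "averaged",
                          initial = list(m = 1, n = 1, state = stq),
                          calibrate_c_target = FALSE)
  df <- tidy(sim)
  ## resting calcium sits below the beating-cell target, so n grows
  expect_gt(glance(sim)$n_final, 1)
  expect_true(all(is.finite(df$cbar_mM)))
})

test_that("snapshot bookkeeping records the requested times", {
  m <- test_model()
  sim <- simulate_coupled(m, "bounded", params = test_params(),
                          drug = drug_block(0.1), t_end_ms = 2 * 3.6e6,
                          snapshot_times_h = c(1, 2), method = "averaged")
  expect_named(sim$snapshots, c("1h", "2h"))
  expect_equal(sim$snapshot_biomarkers$timepoint_h, c(1, 2))
  expect_true(all(c("apd50_ms", "apd80_ms", "beat_rate_bpm", "n") %in%
                    names(sim$snapshot_biomarkers)))
  expect_error(
    simulate_coupled(m, "bounded", params = test_params(),
                     t_end_ms = 3.6e6, snapshot_times_h = c(2, 1)),
    "increasing"
  )
  expect_error(
    simulate_coupled(m, "bounded", params = test_params(),
                     t_end_ms = 3.6e6, snapshot_times_h = 5),
    "horizon"
  )
})
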