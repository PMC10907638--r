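test_that("sigmoid gate matches its closed form and the complement identity", {
  expect_equal(sigmoid_gate(1, 1, 0.01), 0.5)
  expect_equal(sigmoid_gate(0.3, 0.3, 5), 0.5)
  ## saturated gate: argument 10 on the tanh scale
  expect_lt(abs(sigmoid_gate(0.2, 0.1, 0.01) - 1), 1e-8)
  expect_lt(sigmoid_gate(0.1, 0.2, 0.01), 1e-8)
  set.seed(11)
  for (i in 1:50) {
    a <- rnorm(1); b <- rnorm(1); e <- runif(1, 1e-6, 10)
    expect_identical(sigmoid_gate(a, b, e) + sigmoid_gate(b, a, e), 1)
  }
  expect_error(sigmoid_gate(1, 0, 0), "positive")
  expect_error(sigmoid_gate(1, 0, -0.1), "positive")
})

test_that("expression gate is 1 on the interior plateau and 0 in the corner regimes", {
  p <- regulation_params(c_target_mM = 2e-4)
  ## midway between the bounds, for calcium on both sides of the target
  for (c_ in c(1e-6, 1e-4, 2e-4, 3e-4, 4e-4)) {
    expect_lt(abs(expression_gate(c_, 1.55, p) - 1), 1e-9)
  }
  ## growth demanded at the upper bound: n > n+, c < c*
  expect_lt(expression_gate(2e-4 - 10 * p$eps_c_mM, p$n_plus + 10 * p$eps_n, p),
            1e-8)
  ## decay demanded at the lower bound: n < n-, c > c*
  expect_lt(expression_gate(2e-4 + 10 * p$eps_c_mM, p$n_minus - 10 * p$eps_n, p),
            1e-8)
  ## c at the target with n interior: the two c-gates are each 1/2
  expect_lt(abs(expression_gate(2e-4, 1.0, p) - 1), 1e-9)
  ## range property over random inputs
  set.seed(12)
  cc <- runif(200, 0, 6e-4); nn <- runif(200, -0.5, 4)
  H <- expression_gate(cc, nn, p)
  expect_true(all(H >= 0 & H <= 1))
})

test_that("two-equation right-hand side reproduces its closed form", {
  p <- regulation_params(c_target_mM = 2e-4)
  ## fixed point
  r <- two_ode_rhs(m = 1, n = 1, c = 2e-4, p)
  expect_equal(r$dm_dt, 0)
  expect_equal(r$dn_dt, 0)
  ## calcium 1e-4 mM below target, tau_m = 400 mM ms
  r <- two_ode_rhs(m = 1, n = 1, c = 2e-4 - 1e-4, p)
  expect_equal(r$dm_dt, 2.5e-7)
  ## mRNA surplus, tau_n = 1000 ms
  r <- two_ode_rhs(m = 1.2, n = 1.0, c = 2e-4, p)
  expect_equal(r$dn_dt, 2e-4)
  expect_equal(sign(two_ode_rhs(1, 1, 1e-4, p)$dm_dt), 1)
  expect_equal(sign(two_ode_rhs(1, 1, 3e-4, p)$dm_dt), -1)
})

test_that("bounded scalar right-hand side vanishes at the target and at the bounds", {
  p <- regulation_params(c_target_mM = 2e-4)
  expect_equal(bounded_scalar_rhs(n = 0.5, c = 2e-4, p), 0)
  expect_equal(bounded_scalar_rhs(n = 2.9, c = 2e-4, p), 0)
  ## growth below target in the interior
  expect_gt(bounded_scalar_rhs(n = 1, c = 1.5e-4, p), 0)
  ## gate shuts growth just above the upper bound
  expect_lt(abs(bounded_scalar_rhs(n = p$n_plus + 10 * p$eps_n,
                                   c = 2e-4 - 5e-5, p)), 1e-12)
  ## sign equals sign(c* - c) wherever the gate is open
  set.seed(13)
  for (i in 1:50) {
    n <- runif(1, 0.3, 2.8); c_ <- runif(1, 5e-5, 3.5e-4)
    r <- bounded_scalar_rhs(n, c_, p)
    if (abs(c_ - 2e-4) > 1e-6) expect_equal(sign(r), sign(2e-4 - c_))
  }
})

test_that("Gronwall envelope has the right endpoints and asymptote", {
  p <- regulation_params(c_target_mM = 2e-4)
  expect_equal(gronwall_bound(0, p0 = 0.3, cdev_sup = 5e-5, p), 0.3)
  ## large-time limit (tau_n/tau_m) * sup|c*-c| = 1000/400 * 5e-5
  expect_equal(gronwall_bound(1e9, p0 = 0.3, cdev_sup = 5e-5, p), 1.25e-4,
               tolerance = 1e-6)
  ## pure decay when the calcium deviation vanishes
  tt <- c(0, 500, 2000, 10000)
  expect_equal(gronwall_bound(tt, p0 = 0.2, cdev_sup = 0, p),
               0.2 * exp(-tt / 1000))
  expect_error(gronwall_bound(-1, 0.1, 0, p), "non-negative")
})

test_that("predicted equilibrium is min(1/b, n_plus)", {
  expect_equal(predicted_equilibrium_n(0.1, Inf), 10)
  expect_equal(predicted_equilibrium_n(0.1, 3), 3)
  expect_equal(predicted_equilibrium_n(1, 3), 1)
  expect_equal(predicted_equilibrium_n(0.45, 3), 1 / 0.45)
  expect_error(predicted_equilibrium_n(0), "\\(0, 1\\]")
  expect_error(predicted_equilibrium_n(-0.2), "\\(0, 1\\]")
})

test_that("regulation parameter validation rejects bad values", {
  expect_error(regulation_params(tau_m_mM_ms = -400), "positive")
  expect_error(regulation_params(eps_n = 0), "positive")
  expect_error(regulation_params(n_minus = 3, n_plus = 0.1), "n_minus < n_plus")
  expect_error(regulation_params(c_target_mM = -1), "positive")
  expect_s3_class(regulation_params(), "regulation_params")
})
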