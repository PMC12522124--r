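test_that("rate equations satisfy the stated limits and exact conservation", {
  g <- test_geometry(); p <- test_params()
  # no exchange: k_a = 0 and empty membrane
  d0 <- rate_equations(compartment_state(0.01, 0, 0),
                       kinetic_params(0, 5e-4, 0.02), g)
  expect_equal(unname(d0), c(0, 0, 0))
  # saturated membrane: adsorption terms vanish
  ds <- rate_equations(compartment_state(0.01, p$c_sat, 0.002), p, g)
  expect_equal(ds[["dc_m"]], -p$k_d * p$c_sat)
  expect_equal(ds[["dc_o"]], g$phi_mem / g$phi_out * p$k_d / 2 * p$c_sat)
  # conservation on random states, against the symbolic flux-sum oracle
  set.seed(11)
  for (i in 1:25) {
    st <- compartment_state(runif(1, 0, 0.05), runif(1, 0, p$c_sat),
                            runif(1, 0, 0.05))
    d <- rate_equations(st, p, g)
    wsum <- g$phi_out * d[["dc_o"]] + g$phi_mem * d[["dc_m"]] +
      g$phi_in * d[["dc_i"]]
    expect_equal(wsum, conservation_residual(st, p, g) -
                   conservation_residual(st, p, g), tolerance = 1e-14)
    expect_lt(abs(wsum), 1e-14)
  }
  bad <- structure(list(k_a = 1, k_d = 1e-3, c_sat = 0), class = "kinetic_params")
  expect_error(rate_equations(compartment_state(0.01, 0, 0), bad, g), "c_sat")
})

test_that("simulated trajectories conserve mass, respect saturation and equilibrate", {
  g <- test_geometry()
  cases <- list(kinetic_params(0.05, 5e-4, 0.02),
                kinetic_params(0.5, 2e-3, 0.1),
                kinetic_params(0.01, 1e-3, 0.005))
  for (p in cases) {
    # horizon far beyond the slow translocation mode, which the membrane
    # saturation factor throttles well below k_d in deeply saturated regimes
    times <- exp(seq(log(0.01 / p$k_a), log(1000 / p$k_d), length.out = 80))
    traj <- simulate_kinetics(p, g, 0.01, times)
    tot <- g$phi_out * traj$c_o + g$phi_mem * traj$c_m + g$phi_in * traj$c_i
    expect_lt(max(abs(tot / 0.01 - 1)), 1e-8)
    expect_true(all(traj$c_m <= p$c_sat * (1 + 1e-7)))
    # passive equilibration: c_i -> c_o
    n <- nrow(traj)
    expect_equal(traj$c_i[n] / traj$c_o[n], 1, tolerance = 1e-6)
    # closed-form equilibrium matches the ODE long-time limit
    eq <- equilibrium_state(p, g, 0.01)
    expect_equal(traj$c_m[n], eq$c_m, tolerance = 1e-6)
    expect_equal(traj$c_o[n], eq$c_o, tolerance = 1e-6)
    # LUV-integrated amount is monotone non-decreasing from empty start
    # (up to integrator tolerance on the flat equilibrium plateau)
    amount <- g$phi_mem * traj$c_m + g$phi_in * traj$c_i
    expect_gt(min(diff(amount)), -1e-8 * max(amount))
  }
})

test_that("k_a = 0 leaves all polymer outside", {
  g <- test_geometry()
  traj <- simulate_kinetics(kinetic_params(0, 5e-4, 0.02), g, 0.01,
                            times = c(1, 10, 1000))
  expect_equal(traj$c_m, rep(0, 3))
  expect_equal(traj$c_i, rep(0, 3))
  expect_equal(traj$c_o, rep(0.01 / g$phi_out, 3))
})

test_that("stiff solver agrees with a naive fixed-step RK4 oracle", {
  g <- test_geometry()
  presets <- list(kinetic_params(0.05, 0.005, 0.02),
                  kinetic_params(0.1, 0.02, 0.05),
                  kinetic_params(0.02, 0.01, 0.01),
                  kinetic_params(0.2, 0.05, 0.1),
                  kinetic_params(0.05, 0.025, 0.003))
  for (p in presets) {
    h <- 1e-4 * min(1 / p$k_a, 1 / p$k_d)
    oracle <- rk4_trajectory(p, g, 0.01, t_end = 0.5 / p$k_d, h = h)
    traj <- simulate_kinetics(p, g, 0.01, times = oracle$time)
    expect_equal(traj$c_m, oracle$c_m, tolerance = 1e-4)
    expect_equal(traj$c_o, oracle$c_o, tolerance = 1e-4)
    expect_equal(traj$c_i, oracle$c_i, tolerance = 1e-4)
  }
})

test_that("compiled and R right-hand sides integrate identically", {
  g <- test_geometry(); p <- test_params()
  times <- exp(seq(log(1), log(2e4), length.out = 40))
  a <- simulate_kinetics(p, g, 0.01, times, engine = "compiled")
  b <- simulate_kinetics(p, g, 0.01, times, engine = "R")
  expect_equal(a$c_m, b$c_m, tolerance = 1e-7)
  expect_equal(a$c_i, b$c_i, tolerance = 1e-7)
})

test_that("equilibrium closed form obeys its limiting regimes", {
  g <- test_geometry()
  # vanishing uptake: c_m -> 0, uniform aqueous concentration
  eq0 <- equilibrium_state(kinetic_params(1e-12, 1, 0.02), g, 0.01)
  expect_equal(eq0$c_m, 0, tolerance = 1e-9)
  expect_equal(eq0$c_o, 0.01 / (g$phi_out + g$phi_in), tolerance = 1e-6)
  # linear-partition limit: c_m/c_o -> 2 k_a/k_d as c_sat -> infinity
  p <- kinetic_params(0.05, 5e-4, Inf)
  eqInf <- equilibrium_state(p, g, 0.01)
  expect_equal(eqInf$c_m / eqInf$c_o, 2 * p$k_a / p$k_d, tolerance = 1e-12)
  expect_error(equilibrium_state(kinetic_params(0.1, 0, 0.02), g, 0.01), "k_d")
})

test_that("integrated fraction normalizes at t_max and matches direct recomputation", {
  g <- test_geometry(); p <- test_params()
  times <- exp(seq(log(0.1), log(2e4), length.out = 60))
  traj <- simulate_kinetics(p, g, 0.01, times)
  f <- integrated_fraction(traj)
  expect_equal(f[length(f)], 1)
  expect_lt(f[1], 0.01)
  direct <- (g$phi_mem * traj$c_m + g$phi_in * traj$c_i) /
    (g$phi_mem * traj$c_m[60] + g$phi_in * traj$c_i[60])
  expect_equal(f, direct, tolerance = 1e-14)
  # no uptake at all -> signalled
  t0 <- simulate_kinetics(kinetic_params(0, 1e-3, 0.02), g, 0.01, c(1, 10))
  expect_error(integrated_fraction(t0), "no uptake")
})

test_that("limiting slopes respond monotonically to k_a and k_d", {
  g <- test_geometry()
  slopes_for <- function(ka, kd) {
    p <- kinetic_params(ka, kd, 0.02)
    times <- exp(seq(log(0.01 / ka), log(5 / kd), length.out = 120))
    limiting_slopes(simulate_kinetics(p, g, 0.01, times))
  }
  ka_vals <- 0.02 * 2^(0:4)
  init <- sapply(ka_vals, function(ka) abs(slopes_for(ka, 5e-4)$initial))
  expect_true(all(diff(init) > 0))
  kd_vals <- 2e-4 * 2^(0:4)
  term <- sapply(kd_vals, function(kd) abs(slopes_for(0.05, kd)$terminal))
  expect_true(all(diff(term) > 0))
})

test_that("flat uptake curves are flagged as degenerate", {
  g <- test_geometry(); p <- test_params()
  traj <- simulate_kinetics(p, g, 0.01, times = seq(9.9e5, 1e6, length.out = 20))
  # fully saturated stretch: log(1 - f) is non-finite nearly everywhere
  expect_error(suppressWarnings(limiting_slopes(traj)), "degenerate")
})

test_that("molecules per vesicle follow the unit-conversion oracle", {
  g <- test_geometry(); p <- test_params()
  traj <- simulate_kinetics(p, g, 0.01, times = c(10, 1e4))
  n2 <- molecules_per_vesicle(traj, mw = 2)
  n4 <- molecules_per_vesicle(traj, mw = 4)
  expect_equal(n2$n_mem, 2 * n4$n_mem, tolerance = 1e-12)
  expect_equal(n2$n_in, 2 * n4$n_in, tolerance = 1e-12)
  # hand computation: mass fraction -> g -> mol -> molecules for one point
  c_m <- traj$c_m[2]
  hand <- c_m * g$v_mem * 1e-21 / 2000 * 6.02214076e23
  expect_equal(n2$n_mem[2], hand, tolerance = 1e-12)
  zero <- simulate_kinetics(kinetic_params(0, 1e-3, 0.02), g, 0.01, c(1, 10))
  expect_equal(molecules_per_vesicle(zero, 2)$n_mem, c(0, 0))
})

test_that("translocation time brackets the (1 - 1/e) crossing", {
  g <- test_geometry()
  p <- test_params()
  times <- exp(seq(log(0.1), log(1e5), length.out = 100))
  tt <- translocation_time(simulate_kinetics(p, g, 0.01, times))
  expect_false(tt$censored)
  # grid refinement moves the located time by < 1%
  fine <- exp(seq(log(0.1), log(1e5), length.out = 1000))
  tt_fine <- translocation_time(simulate_kinetics(p, g, 0.01, fine))
  expect_lt(abs(tt$time / tt_fine$time - 1), 0.01)
  # faster desorption translocates no later
  kd_vals <- 2e-4 * 2^(0:4)
  tstars <- sapply(kd_vals, function(kd) {
    tr <- simulate_kinetics(kinetic_params(0.05, kd, 0.02), g, 0.01, times)
    translocation_time(tr)$time
  })
  expect_true(all(diff(tstars) <= 1e-9 * tstars[-1] + 0))
  # no adsorption: censored at the last grid time
  cen <- translocation_time(
    simulate_kinetics(kinetic_params(0, 1e-3, 0.02), g, 0.01, c(1, 10)))
  expect_true(cen$censored)
  expect_equal(cen$time, 10)
})

test_that("partition coefficient reproduces its limits and the ODE oracle", {
  g <- test_geometry()
  expect_lt(partition_coefficient(kinetic_params(1e-10, 1, 0.02), g, 0.01), 1e-8)
  p_inf <- kinetic_params(0.05, 5e-4, Inf)
  expect_equal(partition_coefficient(p_inf, g, 0.01),
               2 * p_inf$k_a / p_inf$k_d, tolerance = 1e-12)
  p <- test_params()
  ratio_sim <- {
    tr <- simulate_kinetics(p, g, 0.01, c(1, 1000 / p$k_d))
    tr$c_m[2] / tr$c_o[2]
  }
  expect_equal(partition_coefficient(p, g, 0.01), ratio_sim, tolerance = 1e-6)
})

test_that("uptake is pointwise monotone in k_a and membrane count in c_sat", {
  g <- test_geometry()
  times <- exp(seq(log(1), log(1e4), length.out = 40))
  amount <- function(ka, csat) {
    tr <- simulate_kinetics(kinetic_params(ka, 5e-4, csat), g, 0.01, times)
    g$phi_mem * tr$c_m + g$phi_in * tr$c_i
  }
  a1 <- amount(0.02, 0.02); a2 <- amount(0.04, 0.02); a3 <- amount(0.08, 0.02)
  expect_true(all(a2 >= a1 * (1 - 1e-9)))
  expect_true(all(a3 >= a2 * (1 - 1e-9)))
  m1 <- simulate_kinetics(kinetic_params(0.05, 5e-4, 0.01), g, 0.01, times)$c_m
  m2 <- simulate_kinetics(kinetic_params(0.05, 5e-4, 0.03), g, 0.01, times)$c_m
  expect_true(all(m2 >= m1 * (1 - 1e-9)))
})
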