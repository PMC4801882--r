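test_that("derivatives reduce to the source alone in an empty system", {
  p <- ctrl_params()
  d <- population_derivatives(population_state(), p)
  expect_equal(d[["B_oe"]], p[["S"]])
  expect_equal(unname(d[-1L]), rep(0, 4))
})

test_that("the logistic proliferation term vanishes at carrying capacity", {
  p <- ctrl_params()
  st <- population_state(B_oe = p[["K"]])
  d <- population_derivatives(st, p)
  expect_equal(d[["B_oe"]], p[["S"]] - p[["delta_oe"]] * p[["K"]])
})

test_that("derivatives reject invalid states and parameters", {
  p <- ctrl_params()
  expect_error(population_state(B_oe = -1), class = "bcd_invalid_input")
  bad <- unclass(p); bad["K"] <- 0
  expect_error(population_derivatives(population_state(), kinetic_params(bad)),
               class = "bcd_invalid_input")
})

test_that("mass balance: the derivative sum equals source + births - losses", {
  set.seed(101)
  p_list <- replicate(5, random_params(), simplify = FALSE)
  for (p in p_list) {
    st <- population_state(runif(5, 0, 3e6))
    d <- population_derivatives(st, p)
    lam <- 1 - (st[["B_oe"]] + st[["B_Mrec"]]) / p[["K"]]
    expected <- p[["S"]] + p[["gamma"]] * lam * st[["B_oe"]] -
      p[["mu_i"]] * st[["B_i"]] - p[["mu_t"]] * st[["B_t"]] -
      p[["mu_re"]] * st[["B_Mrec"]] - p[["eps_spl"]] * st[["B_Mspl"]]
    expect_equal(sum(d), expected, tolerance = 1e-12)
  }
})

test_that("steady state satisfies the convergence criterion and calibration", {
  for (group in c("control", "depleted")) {
    p <- default_params(group)
    ss <- find_steady_state(p)
    d <- population_derivatives(ss, p)
    expect_lt(max(abs(d) / (as.numeric(ss) + 1)), 1e-8)
    # round-trip with the calibration targets, within 1%
    expect_equal(as.numeric(ss), as.numeric(attr(p, "totals")),
                 tolerance = 0.01)
  }
})

test_that("a source-free system with positive loss rates decays to zero", {
  p <- unclass(ctrl_params())
  p["S"] <- 0
  ss <- find_steady_state(kinetic_params(p))
  expect_equal(unname(as.numeric(ss)), rep(0, 5), tolerance = 1e-6)
})

test_that("steady-state immature total is monotone in the source", {
  p1 <- unclass(ctrl_params())
  p2 <- p1; p2["S"] <- 2 * p1["S"]
  s1 <- find_steady_state(kinetic_params(p1))
  s2 <- find_steady_state(kinetic_params(p2))
  expect_gte(s2[["B_i"]], s1[["B_i"]])
})

test_that("steady state is invariant under 100 further time units", {
  p <- ctrl_params()
  ss <- find_steady_state(p)
  opts <- steady_state_options()
  out <- bcelldyn:::.ode(setNames(as.numeric(ss), state_names()),
                         c(0, 100), "bcd_derivs_pop", p, opts)
  later <- as.numeric(out[nrow(out), -1L])
  expect_equal(later, as.numeric(ss), tolerance = 1e-6)
})

test_that("non-convergence within the horizon is an explicit failure", {
  p <- ctrl_params()
  expect_error(find_steady_state(p, steady_state_options(max_time = 4)),
               class = "bcd_no_convergence")
})

test_that("integration from non-negative states stays non-negative", {
  set.seed(202)
  opts <- steady_state_options()
  for (i in 1:5) {
    p <- random_params()
    y0 <- setNames(runif(5, 0, 1e6), state_names())
    out <- bcelldyn:::.ode(y0, seq(0, 50, by = 10), "bcd_derivs_pop", p, opts)
    expect_gte(min(out[, -1L]), -opts$atol)
  }
})

test_that("compiled and R-side derivatives agree along a trajectory", {
  p <- ctrl_params()
  opts <- steady_state_options()
  y0 <- setNames(c(1e5, 2e5, 1e5, 1e6, 5e6), state_names())
  out_c <- bcelldyn:::.ode(y0, 0:20, "bcd_derivs_pop", p, opts)
  fn <- function(t, y, parms)
    list(unname(population_derivatives(population_state(y), p)))
  out_r <- deSolve::lsoda(y0, 0:20, fn, rtol = opts$rtol, atol = opts$atol)
  expect_equal(unname(out_c[, -1L]), unname(out_r[, -1L]), tolerance = 1e-6)
})

test_that("depletion multiplies compartments by their survival fractions", {
  st <- population_state(1e6, 4e5, 7e5, 3e6, 2e7)
  expect_equal(as.numeric(apply_depletion(st, depletion_spec(1, 1, 1, 1, 1))),
               as.numeric(st))
  dep <- apply_depletion(st)  # default anti-CD20 pattern
  expect_equal(as.numeric(dep),
               c(1e6, 2e5, 0, 0, 0))
  expect_equal(as.numeric(apply_depletion(st, depletion_spec(0, 0, 0, 0, 0))),
               rep(0, 5))
  # idempotent for all-or-nothing survival
  bin <- depletion_spec(1, 0, 0, 1, 0)
  once <- apply_depletion(st, bin)
  expect_equal(as.numeric(apply_depletion(once, bin)), as.numeric(once))
  expect_error(depletion_spec(immature = 1.2), class = "bcd_invalid_input")
})

test_that("residence times are reciprocals of summed death + exit rates", {
  pd <- depl_params()
  expect_equal(round(residence_time(pd, "immature"), 2), 1.13)
  pc <- ctrl_params()
  expect_equal(residence_time(pc, "immature"), 1 / 0.89)
  p <- unclass(pc); p["mu_t"] <- 0.5; p["delta_t"] <- 0.5
  expect_equal(residence_time(kinetic_params(p), "transitional"), 1)
  p["mu_t"] <- 0; p["delta_t"] <- 0
  expect_error(residence_time(kinetic_params(p), "transitional"),
               class = "bcd_undefined_result")
})

test_that("calibration identities hold and infeasible targets signal", {
  r <- table1_rates("control")
  cal <- calibrate_source_and_capacity(r, occupancy = 0.5)
  expect_equal(cal$K,
               (cal$totals[["B_oe"]] + cal$totals[["B_Mrec"]]) / 0.5)
  # no proliferation: the source exactly balances differentiation
  r0 <- r; r0["gamma"] <- 0
  cal0 <- calibrate_source_and_capacity(r0, occupancy = 0.5)
  expect_equal(cal0$S, r0[["delta_oe"]] * cal0$totals[["B_oe"]])
  # proliferation dominating differentiation implies a negative source
  rbad <- r; rbad["gamma"] <- 2; rbad["delta_oe"] <- 0.1
  expect_error(calibrate_source_and_capacity(rbad, occupancy = 0.5),
               class = "bcd_infeasible_target")
})

test_that("calibrated steady state reproduces the anchored totals", {
  cal <- calibrate_source_and_capacity(table1_rates("control"),
                                       anchor_Mspl = 2e7, occupancy = 0.5)
  ss <- find_steady_state(cal$params)
  expect_equal(as.numeric(ss), as.numeric(cal$totals), tolerance = 1e-4)
})
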