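test_that("LHS places exactly one draw in each equal-width stratum", {
  rng <- parameter_ranges(
    data.frame(parameter = "gamma", lower = 0, upper = 1),
    fixed = setNames(rep(1, 13), setdiff(param_names(), "gamma")))
  x <- lhs_sample(rng, 4, seed = 1)[, "gamma"]
  expect_equal(sort(floor(x * 4)), 0:3)
  # occupancy holds across seeds and larger N
  for (s in 1:10) {
    x <- lhs_sample(rng, 16, seed = s)[, "gamma"]
    expect_equal(sort(floor(x * 16)), 0:15)
  }
})

test_that("LHS is deterministic given the seed and honors degenerate ranges", {
  rng <- narrow_ranges("control")
  a <- lhs_sample(rng, 25, seed = 7)
  b <- lhs_sample(rng, 25, seed = 7)
  expect_identical(a, b)
  c2 <- lhs_sample(rng, 25, seed = 8)
  expect_false(identical(a, c2))
  deg <- parameter_ranges(
    data.frame(parameter = "gamma", lower = 0.3, upper = 0.3),
    fixed = setNames(rep(1, 13), setdiff(param_names(), "gamma")))
  expect_equal(lhs_sample(deg, 6, seed = 3)[, "gamma"], rep(0.3, 6))
})

test_that("the steady-state filter keeps exactly the in-range candidates", {
  rng <- narrow_ranges("control")
  cand <- lhs_sample(rng, 8, seed = 5)
  all_pass <- steady_state_filter(cand,
    data.frame(subset = measured_subsets(), lower = 0, upper = Inf))
  expect_true(all(all_pass$pass))
  none <- suppressWarnings(steady_state_filter(cand,
    data.frame(subset = "immature", lower = 0, upper = 0)))
  expect_false(any(none$pass))
  # every passing candidate re-simulated independently lands in range
  ranges <- generate_totals_ranges(ctrl_params(), 0.5)
  flt <- steady_state_filter(cand, ranges)
  for (i in which(flt$pass)) {
    ss <- find_steady_state(kinetic_params(cand[i, ]))
    idx <- match(ranges$subset, subset_names())
    expect_true(all(as.numeric(ss)[idx] >= ranges$lower &
                      as.numeric(ss)[idx] <= ranges$upper))
  }
  expect_error(steady_state_filter(cand,
    data.frame(subset = "immature", lower = 2, upper = 1)),
    class = "bcd_invalid_input")
})

test_that("log-likelihood matches brute-force Gaussian density summation", {
  p <- ctrl_params()
  design <- experiment_design("control")
  data <- tiny_cohort("control")
  pred <- bcelldyn:::predict_fractions(p, design)
  # fixed sd: per-row oracle
  ll <- log_likelihood(p, data, design, noise_model(sd = 0.05))
  oracle <- sum(vapply(seq_len(nrow(data)), function(k)
    dnorm(data$labeled_fraction[k],
          pred[as.character(data$day[k]), data$subset[k]], 0.05, log = TRUE),
    numeric(1)))
  expect_equal(ll, oracle, tolerance = 1e-12)
  # row permutation invariance
  perm <- data[sample(nrow(data)), ]
  expect_equal(log_likelihood(p, perm, design, noise_model(sd = 0.05)), ll,
               tolerance = 1e-12)
})

test_that("profiled noise sd attains the fixed-sd maximum", {
  p <- ctrl_params()
  design <- experiment_design("control")
  data <- tiny_cohort("control")
  ll_prof <- log_likelihood(p, data, design, noise_model())
  # profiled lnL must dominate every common fixed sd
  lls <- vapply(seq(0.005, 0.2, by = 0.005), function(s)
    log_likelihood(p, data, design, noise_model(sd = s)), numeric(1))
  expect_gte(ll_prof, max(lls))
})

test_that("data exactly on the predictions gives the zero-residual likelihood", {
  p <- ctrl_params()
  design <- experiment_design("control")
  spec <- cohort_spec(params = list(control = p),
                      designs = list(control = design),
                      n_mice = 3, sd = 0, seed = 1)
  data <- generate_cohort(spec)
  n <- nrow(data)
  ll <- log_likelihood(p, data, design, noise_model(sd = 0.03))
  expect_equal(ll, -n * log(0.03 * sqrt(2 * pi)), tolerance = 1e-6)
  # moving one datum away strictly decreases lnL, monotonically
  lls <- vapply(c(0.01, 0.05, 0.1), function(shift) {
    d2 <- data
    d2$labeled_fraction[1] <- min(1, d2$labeled_fraction[1] + shift)
    log_likelihood(p, d2, design, noise_model(sd = 0.03))
  }, numeric(1))
  expect_true(all(diff(c(ll, lls)) < 0))
})

test_that("fit_mle returns the likelihood argmax deterministically", {
  data <- tiny_cohort("control")
  design <- experiment_design("control")
  rng <- narrow_ranges("control")
  fit <- fit_mle(data, rng, N = 30, seed = 21, design = design)
  expect_s3_class(fit, "bcell_fit")
  # argmax agrees with brute-force over the evaluated candidates
  expect_equal(fit$lnL, max(fit$lnL_all, na.rm = TRUE))
  fit2 <- fit_mle(data, rng, N = 30, seed = 21, design = design)
  expect_identical(unclass(fit$params), unclass(fit2$params))
  # N = 1 returns the lone candidate regardless of fit quality
  fit1 <- fit_mle(data, rng, N = 1, seed = 3, design = design)
  expect_equal(fit1$n_evaluated, 1L)
  expect_true(is.finite(fit1$lnL))
})

test_that("a candidate set containing the truth recovers it on noise-free data", {
  p <- ctrl_params()
  design <- experiment_design("control")
  spec <- cohort_spec(params = list(control = p),
                      designs = list(control = design),
                      n_mice = 2, sd = 0, seed = 2)
  data <- generate_cohort(spec)
  # degenerate ranges collapse every candidate onto the truth
  truth <- data.frame(parameter = rate_names(),
                      lower = unclass(p)[rate_names()],
                      upper = unclass(p)[rate_names()])
  rng <- parameter_ranges(truth, fixed = c(S = p[["S"]], K = p[["K"]]))
  fit <- fit_mle(data, rng, N = 3, seed = 4, design = design,
                 noise = noise_model(sd = 0.03))
  expect_equal(unclass(fit$params), unclass(p), tolerance = 1e-12,
               ignore_attr = TRUE)
  # and no broader fit can beat the truth's zero-residual likelihood
  wide <- fit_mle(data, narrow_ranges("control"), N = 30, seed = 5,
                  design = design, noise = noise_model(sd = 0.03))
  expect_lte(wide$lnL, fit$lnL + 1e-9)
})

test_that("an empty filter pass-set is an explicit failure", {
  data <- tiny_cohort("control")
  design <- experiment_design("control")
  expect_error(
    suppressWarnings(fit_mle(data, narrow_ranges("control"), N = 5,
                             seed = 1, design = design,
      total_ranges = data.frame(subset = "immature", lower = 0, upper = 0))),
    class = "bcd_no_candidates")
})

test_that("the profile cutoff is the chi-squared(1) quantile", {
  expect_equal(round(profile_cutoff(0.05), 2), 3.84)
  expect_error(profile_cutoff(1.2), class = "bcd_invalid_input")
})

test_that("profiling a quadratic likelihood reproduces the Wald interval", {
  # analytic Gaussian-mean problem routed through the profile engine
  m <- 0.3; se <- 0.02
  objective <- function(theta) -0.5 * ((theta[["gamma"]] - m) / se)^2
  sampled <- data.frame(parameter = c("gamma", "mu_i"),
                        lower = c(0.1, 0), upper = c(0.5, 1))
  rng <- parameter_ranges(sampled,
    fixed = setNames(rep(1, 12), setdiff(param_names(), c("gamma", "mu_i"))))
  center <- setNames(rep(1, 14), param_names())
  center["gamma"] <- m; center["mu_i"] <- 0.5
  grid <- seq(0.1, 0.5, length.out = 401)
  prof <- bcelldyn:::profile_engine(objective, center, "gamma", rng, grid,
                                    n_draws = 5, rounds = 1, seed = 1)
  ci <- bcelldyn:::ci_from_profile(grid, prof, max(prof), profile_cutoff(0.05))
  expect_equal(ci$lower, m - 1.96 * se, tolerance = 1e-3)
  expect_equal(ci$upper, m + 1.96 * se, tolerance = 1e-3)
  expect_false(ci$censored_lower || ci$censored_upper)
})

test_that("the best fit lies inside its own profile interval", {
  data <- tiny_cohort("control", n_mice = 2, sd = 0.02)
  design <- experiment_design("control")
  rng <- narrow_ranges("control")
  fit <- fit_mle(data, rng, N = 20, seed = 31, design = design)
  ci <- profile_likelihood_ci(fit, "mu_i", data, grid_size = 9,
                              n_draws = 20, rounds = 1, seed = 31)
  expect_lte(ci$lower, fit$params[["mu_i"]])
  expect_gte(ci$upper, fit$params[["mu_i"]])
})

test_that("profile intervals tighten as observation noise shrinks", {
  design <- experiment_design("control")
  rng <- narrow_ranges("control")
  width <- vapply(c(0.06, 0.015), function(s) {
    data <- tiny_cohort("control", n_mice = 4, sd = s, seed = 17)
    fit <- fit_mle(data, rng, N = 20, seed = 41, design = design,
                   noise = noise_model(sd = s))
    ci <- profile_likelihood_ci(fit, "delta_i_t", data, grid_size = 9,
                                n_draws = 25, rounds = 1, seed = 41)
    ci$upper - ci$lower
  }, numeric(1))
  expect_gte(width[1], width[2])
})
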