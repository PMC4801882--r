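# shared fixtures: small parameter sets, designs and cohorts built in code

ctrl_params <- function() default_params("control")
depl_params <- function() default_params("depleted")

# a fast, loose design for fit tests: fewer mice, same days
tiny_cohort <- function(group = "control", n_mice = 2, sd = 0.02,
                        seed = 11) {
  params <- setNames(list(default_params(group)), group)
  designs <- setNames(list(experiment_design(group)), group)
  generate_cohort(cohort_spec(params = params, designs = designs,
                              n_mice = n_mice, sd = sd, seed = seed))
}

# narrow sampling ranges centered on the published best fits, for quick fits
narrow_ranges <- function(group, frac = 0.2) {
  r <- table1_rates(group)
  p <- default_params(group)
  sampled <- data.frame(parameter = names(r),
                        lower = pmax(0, r * (1 - frac)),
                        upper = r * (1 + frac) + 1e-6)
  parameter_ranges(sampled, fixed = c(S = p[["S"]], K = p[["K"]]))
}

# random valid parameter set drawn around the control best fits
random_params <- function() {
  r <- table1_rates("control")
  r <- r * runif(length(r), 0.5, 1.5)
  kinetic_params(c(r, S = 2e5 * runif(1, 0.5, 2), K = 3e6 * runif(1, 0.5, 2)))
}

# sensitivity_sample built directly from matrices (for regression/PRCC
# unit tests that need a known input-output relationship)
make_sample <- function(inputs, outcomes, seed = 0) {
  structure(list(inputs = inputs, outcomes = outcomes, n_failed = 0L,
                 seed = seed), class = "sensitivity_sample")
}

# independent residual-on-residual partial correlation (oracle)
partial_cor_oracle <- function(X, y) {
  vapply(colnames(X), function(v) {
    Z <- X[, setdiff(colnames(X), v), drop = FALSE]
    rx <- if (ncol(Z)) resid(lm(X[, v] ~ Z)) else X[, v]
    ry <- if (ncol(Z)) resid(lm(y ~ Z)) else y
    cor(rx, ry)
  }, numeric(1))
}
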