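#' @name sensitivity
#' @title Global sensitivity analysis of subset totals
#'
#' @description
#' Monte Carlo sensitivity analysis of the steady-state (control) or
#' day-34 post-depletion (depleted) subset totals with respect to the rate
#' parameters and the mouse type: stepwise linear regression reporting the
#' overall Pearson R, R-squared and per-parameter partial correlations, and
#' partial rank correlation coefficients (PRCCs), which measure monotone
#' association after removing the linear effects of the other inputs on
#' ranks.
NULL

#' Build a sensitivity sample over both mouse types
#'
#' For each of `N` Latin-hypercube draws per group, runs the group's
#' protocol — control: steady state; depleted: steady state, depletion,
#' recovery interval — and records the five subset totals. The mouse type
#' enters the input matrix as an indicator (0 = control, 1 = depleted).
#'
#' @param ranges_control,ranges_depleted [parameter_ranges()] per group
#'   (defaults: published-CI ranges via [default_ranges()] with
#'   `widen = 0`). Both groups share the control-derived source and
#'   carrying-capacity constants, so the mouse-type indicator isolates the
#'   protocol effect (depletion plus partial recovery) rather than a
#'   difference in calibration anchors; the depleted rows are then read out
#'   in the partially reconstituted regime the study measured.
#' @param N Draws per group.
#' @param seed Integer seed.
#' @param depletion [depletion_spec()] applied to depleted rows.
#' @param recovery Recovery interval before the depleted read-out (6-h
#'   units; default 136 = 34 days, the study's measurement epoch, since the
#'   depleted populations have not yet returned to steady state there).
#' @param opts [steady_state_options()].
#' @return A `sensitivity_sample`: list with `inputs` (sampled parameters
#'   plus `mouse_type`), `outcomes` (subset totals), `n_failed` (dropped
#'   simulations), `seed`.
#' @export
build_sensitivity_sample <- function(ranges_control = default_ranges("control", widen = 0),
                                     ranges_depleted = default_ranges("depleted", widen = 0,
                                       params = default_params("control")),
                                     N = 1000, seed,
                                     depletion = depletion_spec(),
                                     recovery = 136,
                                     opts = steady_state_options()) {
  if (N < 10) bcd_error("N must be >= 10", "bcd_invalid_input")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, 2L))
  run_group <- function(ranges, sd_seed, type) {
    cand <- lhs_sample(ranges, N, sd_seed)
    out <- matrix(NA_real_, N, 5L, dimnames = list(NULL, subset_names()))
    for (i in seq_len(N)) {
      res <- tryCatch({
        p <- kinetic_params(cand[i, ])
        ss <- find_steady_state(p, opts)
        if (type == 0) as.numeric(ss) else {
          y <- apply_depletion(ss, depletion)
          sol <- .ode(setNames(as.numeric(y), state_names()),
                      c(0, recovery), "bcd_derivs_pop",
                      p, opts)
          pmax(as.numeric(sol[nrow(sol), -1L]), 0)
        }
      }, bcelldyn_error = function(e) NULL)
      if (!is.null(res)) out[i, ] <- res
    }
    sampled <- attr(cand, "sampled")
    list(inputs = cbind(cand[, sampled, drop = FALSE], mouse_type = type),
         outcomes = out)
  }
  ctl <- run_group(ranges_control, seeds[1L], 0)
  dep <- run_group(ranges_depleted, seeds[2L], 1)
  inputs <- rbind(ctl$inputs, dep$inputs)
  outcomes <- rbind(ctl$outcomes, dep$outcomes)
  keep <- stats::complete.cases(outcomes)
  structure(list(inputs = inputs[keep, , drop = FALSE],
                 outcomes = outcomes[keep, , drop = FALSE],
                 n_failed = sum(!keep), seed = seed,
                 ranges = list(control = ranges_control,
                               depleted = ranges_depleted),
                 depletion = depletion, recovery = recovery),
            class = "sensitivity_sample")
}

# partial correlation of each column of X with y, controlling for the other
# columns, via the precision matrix of cor(cbind(y, X)); near-singular cases
# (e.g. an exactly linear outcome) fall back to the residual definition
partial_cor <- function(X, y) {
  R <- cor(cbind(y, X))
  P <- if (rcond(R) > 1e-10) solve(R) else NULL
  if (!is.null(P)) {
    pc <- -P[1L, -1L] / sqrt(P[1L, 1L] * diag(P)[-1L])
  } else {
    pc <- vapply(seq_len(ncol(X)), function(j) {
      q <- qr(cbind(1, X[, -j, drop = FALSE]))
      rx <- qr.resid(q, X[, j])
      ry <- qr.resid(q, y)
      if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
      cor(rx, ry)
    }, numeric(1L))
  }
  setNames(pmin(pmax(pc, -1), 1), colnames(X))
}

check_sample <- function(sample, outcome) {
  if (!inherits(sample, "sensitivity_sample"))
    bcd_error("`sample` must be a sensitivity_sample", "bcd_invalid_input")
  if (nrow(sample$inputs) < 10)
    bcd_error("need at least 10 complete rows", "bcd_invalid_input")
  if (!outcome %in% colnames(sample$outcomes))
    bcd_error(paste0("unknown outcome: ", outcome), "bcd_invalid_input")
}

#' Stepwise linear-regression sensitivity
#'
#' Forward selection of inputs by improvement in R-squared: at each step the
#' input raising R-squared the most is added, until the best improvement
#' falls below `threshold`. Reports the final model's multiple correlation
#' R and R-squared, and each included input's partial correlation with the
#' outcome given the other included inputs.
#'
#' @param sample A `sensitivity_sample` from [build_sensitivity_sample()].
#' @param outcome One of [subset_names()].
#' @param threshold Minimum R-squared improvement for inclusion.
#' @return A `sensitivity_report`: list with `outcome`, `R`, `R2`, `table`
#'   (data frame `parameter`, `partial_R` in inclusion order), `method`,
#'   `threshold`. Signals `bcd_degenerate_result` for a constant outcome.
#' @export
stepwise_regression_sensitivity <- function(sample, outcome,
                                            threshold = 0.01) {
  check_sample(sample, outcome)
  y <- sample$outcomes[, outcome]
  X <- sample$inputs
  if (sd(y) == 0)
    bcd_error("outcome is constant: sensitivity undefined",
              "bcd_degenerate_result")
  vars <- colnames(X)[apply(X, 2L, sd) > 0]
  included <- character()
  r2 <- 0
  repeat {
    rest <- setdiff(vars, included)
    if (!length(rest)) break
    r2_new <- vapply(rest, function(v) {
      r <- qr.resid(qr(cbind(1, X[, c(included, v), drop = FALSE])), y)
      1 - sum(r^2) / sum((y - mean(y))^2)
    }, numeric(1L))
    gain <- r2_new - r2
    if (max(gain) < threshold) break
    pick <- rest[which.max(gain)]
    included <- c(included, pick)
    r2 <- r2_new[[pick]]
  }
  if (!length(included))
    return(structure(list(outcome = outcome, R = 0, R2 = 0,
                          table = data.frame(parameter = character(),
                                             partial_R = numeric()),
                          method = "stepwise-linear", threshold = threshold),
                     class = "sensitivity_report"))
  pc <- partial_cor(X[, included, drop = FALSE], y)
  structure(list(outcome = outcome, R = sqrt(r2), R2 = r2,
                 table = data.frame(parameter = included,
                                    partial_R = unname(pc)),
                 method = "stepwise-linear", threshold = threshold),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("<sensitivity_report> %s: R = %.3f, R2 = %.3f (%s)\n",
              x$outcome, x$R, x$R2, x$method))
  tab <- x$table
  tab$partial_R <- round(tab$partial_R, 3)
  print(tab)
  invisible(x)
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms every input column and the outcome (average ranks on
#' ties), then computes the partial correlation of each input with the
#' outcome controlling for all other inputs.
#'
#' @inheritParams stepwise_regression_sensitivity
#' @return Named numeric vector of PRCCs (one per varying input).
#' @export
prcc <- function(sample, outcome) {
  check_sample(sample, outcome)
  y <- sample$outcomes[, outcome]
  X <- sample$inputs[, apply(sample$inputs, 2L, sd) > 0, drop = FALSE]
  Xr <- apply(X, 2L, rank, ties.method = "average")
  partial_cor(Xr, rank(y, ties.method = "average"))
}
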