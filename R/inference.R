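#' @name inference
#' @title Latin-hypercube maximum-likelihood fitting
#'
#' @description
#' Parameter estimation follows the original study's search strategy: draw
#' candidate rate sets by Latin hypercube sampling (one draw per
#' equal-probability stratum of each parameter's range), discard candidates
#' whose steady-state subset totals fall outside the experimentally observed
#' ranges, evaluate the likelihood of the per-mouse labeled fractions under
#' each surviving candidate, and take the maximizer. Confidence intervals
#' come from the profile likelihood: the 95\% interval contains the values
#' of a parameter for which the likelihood-ratio statistic
#' \eqn{G^2 = 2[\ln L_{best} - \ln L(\theta_0)]} stays below the
#' \eqn{\chi^2(1)} 95th percentile, 3.84.
NULL

#' Parameter ranges for candidate sampling
#'
#' @param sampled Data frame with columns `parameter`, `lower`, `upper` for
#'   every parameter to be sampled.
#' @param fixed Named numeric vector of parameters held fixed (must cover
#'   whatever `sampled` does not so the union is the full parameter set).
#' @return List with class `parameter_ranges`.
#' @export
parameter_ranges <- function(sampled, fixed = numeric()) {
  need <- c("parameter", "lower", "upper")
  if (!is.data.frame(sampled) || !all(need %in% names(sampled)))
    bcd_error("`sampled` needs columns parameter, lower, upper",
              "bcd_invalid_input")
  if (any(sampled$lower > sampled$upper) || any(sampled$lower < 0))
    bcd_error("ranges need 0 <= lower <= upper", "bcd_invalid_input")
  all_names <- c(sampled$parameter, names(fixed))
  if (anyDuplicated(all_names))
    bcd_error("a parameter cannot be both sampled and fixed",
              "bcd_invalid_input")
  missing <- setdiff(param_names(), all_names)
  if (length(missing))
    bcd_error(paste0("no range or fixed value for: ",
                     paste(missing, collapse = ", ")), "bcd_invalid_input")
  structure(list(sampled = sampled[, need], fixed = fixed),
            class = "parameter_ranges")
}

#' Default sampling ranges for a mouse group
#'
#' The published 95\% confidence intervals widened symmetrically by
#' `widen` times their width (floored at 0) for the 11 published rates, the
#' reflux rate `delta_r` sampled on `delta_r_range`, and the source `S` and
#' capacity `K` fixed at the group's calibration defaults.
#'
#' @inheritParams table1_rates
#' @param widen Half-width extension as a fraction of the CI width.
#' @param delta_r_range Sampling range for the reflux rate.
#' @param params Full parameter set supplying the fixed `S` and `K`
#'   (default: [default_params()] for the group).
#' @return A [parameter_ranges()] object.
#' @export
default_ranges <- function(group = c("control", "depleted"), widen = 0.5,
                           delta_r_range = c(0, 0.1),
                           params = default_params(group)) {
  group <- match.arg(group)
  ci <- table1_ci(group)
  w <- ci$upper - ci$lower
  sampled <- data.frame(parameter = ci$parameter,
                        lower = pmax(0, ci$lower - widen * w),
                        upper = ci$upper + widen * w)
  sampled <- rbind(sampled,
                   data.frame(parameter = "delta_r",
                              lower = delta_r_range[1L],
                              upper = delta_r_range[2L]))
  parameter_ranges(sampled,
                   fixed = c(S = params[["S"]], K = params[["K"]]))
}

#' Latin hypercube sample of candidate parameter sets
#'
#' Each sampled parameter's range is divided into `N` equal-width strata and
#' each stratum is sampled exactly once; strata are paired across parameters
#' by random permutation. Deterministic given `seed`.
#'
#' @param ranges A [parameter_ranges()] object.
#' @param N Number of candidates (rows).
#' @param seed Integer seed (mandatory; echoed in the result).
#' @return Numeric matrix `N x 14` (full parameter sets, fixed columns
#'   repeated), with attribute `"seed"`.
#' @export
lhs_sample <- function(ranges, N, seed) {
  if (!inherits(ranges, "parameter_ranges"))
    bcd_error("`ranges` must be a parameter_ranges object",
              "bcd_invalid_input")
  if (N < 1) bcd_error("N must be >= 1", "bcd_invalid_input")
  k <- nrow(ranges$sampled)
  u <- with_seed(seed, lhs::randomLHS(N, k))
  lower <- ranges$sampled$lower
  upper <- ranges$sampled$upper
  sampled <- sweep(sweep(u, 2L, upper - lower, "*"), 2L, lower, "+")
  colnames(sampled) <- ranges$sampled$parameter
  out <- matrix(NA_real_, nrow = N, ncol = length(param_names()),
                dimnames = list(NULL, param_names()))
  out[, colnames(sampled)] <- sampled
  for (nm in names(ranges$fixed)) out[, nm] <- ranges$fixed[[nm]]
  attr(out, "seed") <- seed
  attr(out, "sampled") <- ranges$sampled$parameter
  out
}

#' Filter candidates by steady-state subset totals
#'
#' Keeps candidates whose steady-state totals lie within all supplied
#' ranges. The depleted group is filtered against the same (control) total
#' ranges as the control group, on the premise that a fully reconstituted
#' depleted mouse returns to control cell numbers.
#'
#' @param candidates Candidate matrix from [lhs_sample()].
#' @param total_ranges Data frame with columns `subset`, `lower`, `upper`
#'   (see [generate_totals_ranges()]); only listed subsets constrain.
#' @param opts [steady_state_options()].
#' @return List: `pass` (logical per candidate), `steady_states` (matrix of
#'   totals, `NA` rows where the steady-state search failed), `n_failed`
#'   (failed searches). A candidate that fails the search does not pass.
#' @export
steady_state_filter <- function(candidates, total_ranges = NULL,
                                opts = steady_state_options()) {
  if (!is.null(total_ranges)) {
    if (!all(c("subset", "lower", "upper") %in% names(total_ranges)))
      bcd_error("`total_ranges` needs columns subset, lower, upper",
                "bcd_invalid_input")
    if (any(total_ranges$upper < total_ranges$lower))
      bcd_error("`total_ranges` needs lower <= upper", "bcd_invalid_input")
  }
  N <- nrow(candidates)
  ss <- matrix(NA_real_, N, 5L, dimnames = list(NULL, state_names()))
  pass <- logical(N)
  n_failed <- 0L
  cols <- if (is.null(total_ranges)) integer() else
    subset_index(total_ranges$subset)
  for (i in seq_len(N)) {
    st <- tryCatch(find_steady_state(kinetic_params(candidates[i, ]), opts),
                   bcelldyn_error = function(e) NULL)
    if (is.null(st)) { n_failed <- n_failed + 1L; next }
    ss[i, ] <- as.numeric(st)
    pass[i] <- is.null(total_ranges) ||
      all(ss[i, cols] >= total_ranges$lower & ss[i, cols] <= total_ranges$upper)
  }
  if (!any(pass))
    warning("no candidate passed the steady-state filter")
  list(pass = pass, steady_states = ss, n_failed = n_failed)
}

#' Observation noise model for labeled fractions
#'
#' @param family Only `"gaussian"` is implemented.
#' @param sd Either `NULL` (per-subset standard deviations profiled out by
#'   their closed-form maximum-likelihood values), a single number, or a
#'   named vector with one entry per measured subset.
#' @return List with class `noise_model`.
#' @export
noise_model <- function(family = "gaussian", sd = NULL) {
  family <- match.arg(family)
  if (!is.null(sd) && any(sd <= 0))
    bcd_error("fixed sd must be positive", "bcd_invalid_input")
  structure(list(family = family, sd = sd), class = "noise_model")
}

# lnL of observed fractions given a prediction matrix [day x subset]
loglik_from_pred <- function(pred, data, noise) {
  mu <- pred[cbind(as.character(data$day), data$subset)]
  if (anyNA(mu)) return(-Inf)
  res <- data$labeled_fraction - mu
  if (is.null(noise$sd)) {
    ll <- 0
    for (s in unique(data$subset)) {
      r <- res[data$subset == s]
      s2 <- max(mean(r^2), .Machine$double.eps)
      ll <- ll - length(r) / 2 * (log(2 * pi * s2) + 1)
    }
    ll
  } else {
    sds <- if (length(noise$sd) == 1L && is.null(names(noise$sd)))
      rep(noise$sd, nrow(data)) else unname(noise$sd[data$subset])
    sum(dnorm(res, 0, sds, log = TRUE))
  }
}

check_data <- function(data, design) {
  need <- c("mouse_id", "group", "day", "subset", "labeled_fraction")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    bcd_error(paste0("measurement table needs columns ",
                     paste(need, collapse = ", ")), "bcd_invalid_input")
  d <- data[data$group == design$group, , drop = FALSE]
  if (!nrow(d))
    bcd_error(paste0("no rows for group ", design$group), "bcd_invalid_input")
  if (!all(d$day %in% design$measurement_days) ||
      !all(d$subset %in% design$subsets))
    bcd_error("data days/subsets not covered by the design",
              "bcd_invalid_input")
  if (any(d$labeled_fraction < 0 | d$labeled_fraction > 1))
    bcd_error("labeled fractions must lie in [0, 1]", "bcd_invalid_input")
  d
}

#' Log-likelihood of a measurement table under a parameter set
#'
#' Independent Gaussian errors on per-mouse labeled fractions around the
#' model-predicted fraction at each (day, subset); per-subset standard
#' deviations are profiled out in closed form when not fixed.
#'
#' @param params A [kinetic_params()] set.
#' @param data Measurement table (columns `mouse_id`, `group`, `day`,
#'   `subset`, `labeled_fraction`); only rows of the design's group enter.
#' @param design An [experiment_design()].
#' @param noise A [noise_model()].
#' @param opts [steady_state_options()].
#' @return The log-likelihood; `-Inf` (with attribute `"diagnostic"`) when
#'   the simulation fails.
#' @export
log_likelihood <- function(params, data, design, noise = noise_model(),
                           opts = steady_state_options()) {
  d <- check_data(data, design)
  pred <- tryCatch(predict_fractions(params, design, opts),
                   bcelldyn_error = function(e) e)
  if (inherits(pred, "condition")) {
    ll <- -Inf
    attr(ll, "diagnostic") <- conditionMessage(pred)
    return(ll)
  }
  loglik_from_pred(pred, d, noise)
}

#' Fit the model by filtered Latin-hypercube maximum likelihood
#'
#' @inheritParams log_likelihood
#' @param ranges A [parameter_ranges()] object.
#' @param N Number of LHS candidates.
#' @param seed Integer seed.
#' @param total_ranges Optional steady-state total ranges for
#'   [steady_state_filter()].
#' @return A `bcell_fit`: list with `params` (best fit), `lnL`, `lnL_all`
#'   (per passing candidate), `candidates`, `pass`, `n_evaluated`,
#'   `n_passed`, `n_failed`, `seed`, `ranges`, `noise`, `design`. Ties in
#'   `lnL` resolve to the first candidate in sampling order. Signals
#'   `bcd_no_candidates` if nothing passes the filter.
#' @export
fit_mle <- function(data, ranges, N, seed, design, noise = noise_model(),
                    total_ranges = NULL, opts = steady_state_options()) {
  d <- check_data(data, design)
  cand <- lhs_sample(ranges, N, seed)
  flt <- steady_state_filter(cand, total_ranges, opts)
  idx <- which(flt$pass)
  if (!length(idx))
    bcd_error("no candidate passed the steady-state filter",
              "bcd_no_candidates")
  lnl <- rep(NA_real_, nrow(cand))
  for (i in idx) {
    pred <- tryCatch(
      predict_fractions(kinetic_params(cand[i, ]), design, opts,
                        ss = population_state(flt$steady_states[i, ])),
      bcelldyn_error = function(e) NULL)
    lnl[i] <- if (is.null(pred)) -Inf else loglik_from_pred(pred, d, noise)
  }
  best <- idx[which.max(lnl[idx])]
  structure(list(params = kinetic_params(cand[best, ]), lnL = lnl[best],
                 lnL_all = lnl, candidates = cand, pass = flt$pass,
                 n_evaluated = nrow(cand), n_passed = length(idx),
                 n_failed = flt$n_failed, seed = seed, ranges = ranges,
                 noise = noise, design = design),
            class = "bcell_fit")
}

#' @export
print.bcell_fit <- function(x, ...) {
  cat(sprintf("<bcell_fit> %s group: lnL = %.3f (%d/%d candidates passed, seed %s)\n",
              x$design$group, x$lnL, x$n_passed, x$n_evaluated, x$seed))
  print(signif(unclass(x$params), 3))
  invisible(x)
}

#' Likelihood-ratio cutoff for a profile-likelihood interval
#'
#' @param alpha Significance level; at `alpha = 0.05` the cutoff on
#'   \eqn{G^2} is the \eqn{\chi^2(1)} 95th percentile, 3.84.
#' @return The cutoff value.
#' @export
profile_cutoff <- function(alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1)
    bcd_error("alpha must be in (0, 1)", "bcd_invalid_input")
  qchisq(1 - alpha, df = 1)
}

# generic profile engine: `objective(full_param_vector) -> lnL`. For each
# grid value of `param`, nuisance parameters are re-optimized by LHS draws
# centered on the running conditional best with a shrinking window; returns
# the profiled lnL per grid point.
profile_engine <- function(objective, center, param, ranges, grid,
                           n_draws, rounds, seed) {
  sampled <- ranges$sampled
  other <- setdiff(sampled$parameter, param)
  lo <- setNames(sampled$lower, sampled$parameter)
  hi <- setNames(sampled$upper, sampled$parameter)
  prof <- numeric(length(grid))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(grid)))
  for (g in seq_along(grid)) {
    theta <- center
    theta[param] <- grid[g]
    best_ll <- objective(theta)
    best_th <- theta
    if (length(other)) {
      for (r in seq_len(rounds)) {
        shrink <- 0.5^(r - 1)
        w_lo <- pmax(lo[other], best_th[other] - shrink * (hi - lo)[other] / 2)
        w_hi <- pmin(hi[other], best_th[other] + shrink * (hi - lo)[other] / 2)
        u <- with_seed(seeds[g] + r, lhs::randomLHS(n_draws, length(other)))
        draws <- sweep(sweep(u, 2L, w_hi - w_lo, "*"), 2L, w_lo, "+")
        colnames(draws) <- other
        for (j in seq_len(n_draws)) {
          th <- best_th
          th[other] <- draws[j, ]
          ll <- objective(th)
          if (is.finite(ll) && ll > best_ll) { best_ll <- ll; best_th <- th }
        }
      }
    }
    prof[g] <- best_ll
  }
  prof
}

# read the CI off a profiled lnL curve by linear interpolation of the
# G^2 = cutoff crossings around the profile maximum
ci_from_profile <- function(grid, prof, lnl_max, cutoff) {
  g2 <- 2 * (lnl_max - prof)
  inside <- which(g2 <= cutoff)
  imax <- which.max(prof)
  cross <- function(i0, i1) {
    # interpolate between grid[i0] (inside) and grid[i1] (outside)
    f <- (cutoff - g2[i0]) / (g2[i1] - g2[i0])
    grid[i0] + f * (grid[i1] - grid[i0])
  }
  lo_i <- min(inside); hi_i <- max(inside)
  lower <- if (lo_i == 1L) grid[1L] else cross(lo_i, lo_i - 1L)
  upper <- if (hi_i == length(grid)) grid[length(grid)] else cross(hi_i, hi_i + 1L)
  list(lower = lower, upper = upper,
       censored_lower = lo_i == 1L, censored_upper = hi_i == length(grid),
       grid = data.frame(value = grid, lnL = prof, G2 = g2),
       estimate = grid[imax], lnL_max = lnl_max)
}

#' Profile-likelihood confidence interval for one parameter
#'
#' Fixes the parameter on a grid spanning its sampling range (log-spaced
#' when the range covers more than a decade), re-optimizes all other sampled
#' parameters at each grid point by refined Latin-hypercube search around
#' the conditional best, and returns the interval where
#' \eqn{G^2 = 2[\ln L_{best} - \ln L(\theta_0)]} does not exceed the
#' \eqn{\chi^2(1)} quantile ([profile_cutoff()]). An interval endpoint lying
#' on the range boundary is flagged as censored.
#'
#' @param fit A `bcell_fit` from [fit_mle()].
#' @param param Name of the (sampled) parameter to profile.
#' @inheritParams fit_mle
#' @param grid_size Number of grid points.
#' @param alpha Significance level (0.05 gives the 3.84 cutoff).
#' @param n_draws LHS draws per refinement round for the nuisance
#'   re-optimization.
#' @param rounds Refinement rounds.
#' @param seed Integer seed for the nuisance search.
#' @return List with `lower`, `upper`, censoring flags, the profile `grid`
#'   (value, lnL, G2), `estimate` and `lnL_max`.
#' @export
profile_likelihood_ci <- function(fit, param, data, grid_size = 41,
                                  alpha = 0.05, n_draws = 500, rounds = 2,
                                  seed = fit$seed,
                                  opts = steady_state_options()) {
  if (!inherits(fit, "bcell_fit"))
    bcd_error("`fit` must come from fit_mle()", "bcd_invalid_input")
  sampled <- fit$ranges$sampled
  if (!param %in% sampled$parameter)
    bcd_error(paste0(param, " is not a sampled parameter"),
              "bcd_invalid_input")
  d <- check_data(data, fit$design)
  lo <- sampled$lower[sampled$parameter == param]
  hi <- sampled$upper[sampled$parameter == param]
  grid <- if (lo > 0 && hi / lo > 10)
    exp(seq(log(lo), log(hi), length.out = grid_size))
  else seq(lo, hi, length.out = grid_size)
  objective <- function(theta) {
    pred <- tryCatch(
      predict_fractions(kinetic_params(theta), fit$design, opts),
      bcelldyn_error = function(e) NULL)
    if (is.null(pred)) -Inf else loglik_from_pred(pred, d, fit$noise)
  }
  prof <- profile_engine(objective, unclass(fit$params), param, fit$ranges,
                         grid, n_draws, rounds, seed)
  # the fit's own maximum belongs to the profile by definition
  ci_from_profile(grid, prof, max(prof, fit$lnL), profile_cutoff(alpha))
}
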