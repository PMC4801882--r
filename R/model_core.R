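#' @name model_core
#' @title Five-compartment population model
#'
#' @description
#' Deterministic dynamics of the five B-cell compartments. Pro-/pre-B cells
#' (`B_oe`) are fed by a constant source `S` and proliferate at rate
#' \eqn{\gamma B_{oe} (1 - (B_{oe}+B_{Mrec})/K)}: proliferation is throttled
#' logistically by the joint occupancy of the pro-/pre-B and BM mature
#' recirculating compartments, which compete for the same bone-marrow
#' survival niches. Downstream compartments exchange by first-order
#' differentiation, flow and death; all rates are per 6-h unit.
NULL

# parameters as the unnamed double vector handed to the compiled RHS
.parvec <- function(params) as.numeric(unclass(params)[param_names()])

.ode <- function(y, times, func, params, opts) {
  deSolve::lsoda(y = y, times = times, func = func, parms = .parvec(params),
                 dllname = "bcelldyn", initfunc = "bcd_initmod",
                 rtol = opts$rtol, atol = opts$atol)
}

#' Per-compartment rates of change
#'
#' Pure-R evaluation of the model right-hand side (the integrator uses an
#' equivalent compiled version).
#'
#' @param state A [population_state()] (non-negative cell counts).
#' @param params A [kinetic_params()] set.
#' @return Named numeric vector of derivatives (cells per 6 h).
#' @examples
#' p <- default_params("control")
#' population_derivatives(population_state(), p)  # empty system: only S
#' @export
population_derivatives <- function(state, params) {
  validate_params(params)
  s <- validate_state(state)
  p <- as.list(unclass(params))
  lam <- 1 - (s[["B_oe"]] + s[["B_Mrec"]]) / p$K
  out_i <- p$mu_i + p$delta_i_t + p$delta_r + p$delta_i_re
  c(B_oe = p$S + p$gamma * lam * s[["B_oe"]] - p$delta_oe * s[["B_oe"]] +
      p$delta_r * s[["B_i"]],
    B_i = p$delta_oe * s[["B_oe"]] - out_i * s[["B_i"]],
    B_Mrec = p$delta_i_re * s[["B_i"]] + p$phi_s * s[["B_Mspl"]] -
      (p$mu_re + p$phi_BM) * s[["B_Mrec"]],
    B_t = p$delta_i_t * s[["B_i"]] - (p$mu_t + p$delta_t) * s[["B_t"]],
    B_Mspl = p$delta_t * s[["B_t"]] + p$phi_BM * s[["B_Mrec"]] -
      (p$phi_s + p$eps_spl) * s[["B_Mspl"]])
}

#' Options for steady-state search and integration
#'
#' @param tol Convergence tolerance on the maximum relative derivative
#'   \eqn{|dB/dt|/(B+1)} per 6 h.
#' @param max_time Maximum simulated time (6-h units) before the search is
#'   declared non-convergent.
#' @param chunk Integration chunk length between convergence checks.
#' @param rtol,atol Relative / absolute integrator tolerances (cells).
#' @return List of options.
#' @export
steady_state_options <- function(tol = 1e-8, max_time = 4000, chunk = 400,
                                 rtol = 1e-8, atol = 1e-3) {
  if (tol <= 0 || max_time <= 0 || chunk <= 0)
    bcd_error("tolerances and horizons must be positive", "bcd_invalid_input")
  list(tol = tol, max_time = max_time, chunk = chunk, rtol = rtol, atol = atol)
}

#' Find the steady state by forward integration
#'
#' Integrates the totals model from the all-zero state (the protocol used
#' before any labeling or depletion is applied) until every compartment's
#' relative derivative falls below `opts$tol`.
#'
#' @inheritParams population_derivatives
#' @param opts [steady_state_options()].
#' @return A [population_state()] with attribute `"time"` (units simulated).
#'   Signals an error of class `bcd_no_convergence` if the criterion is not
#'   met within `opts$max_time`.
#' @export
find_steady_state <- function(params, opts = steady_state_options()) {
  validate_params(params)
  y <- setNames(numeric(5L), state_names())
  t_done <- 0
  while (t_done < opts$max_time) {
    step <- min(opts$chunk, opts$max_time - t_done)
    out <- .ode(y, c(0, step), "bcd_derivs_pop", params, opts)
    y <- setNames(as.numeric(out[nrow(out), -1L]), state_names())
    y[y < 0] <- 0  # clip solver undershoot at the scale of atol
    t_done <- t_done + step
    d <- population_derivatives(population_state(y), params)
    if (max(abs(d) / (y + 1)) < opts$tol) {
      st <- population_state(y)
      attr(st, "time") <- t_done
      return(st)
    }
  }
  bcd_error(sprintf(
    "steady state not reached within %g time units (max relative derivative %.3g)",
    opts$max_time, max(abs(d) / (y + 1))), "bcd_no_convergence")
}

#' Depletion specification
#'
#' Survival fraction per compartment applied instantaneously by
#' [apply_depletion()]. The defaults reproduce the observed anti-hCD20
#' depletion pattern: pro-/pre-B cells do not express hCD20 and are spared,
#' about half of immature cells are eliminated, and the mature circulating,
#' transitional and splenic mature pools are fully depleted.
#'
#' @param pro_pre,immature,mature_recirculating,transitional,splenic_mature
#'   Survival fractions in \[0, 1\].
#' @return Named numeric vector of length 5 with class `depletion_spec`
#'   (names in state order).
#' @export
depletion_spec <- function(pro_pre = 1, immature = 0.5,
                           mature_recirculating = 0, transitional = 0,
                           splenic_mature = 0) {
  if (length(pro_pre) == 5L) {
    f <- if (is.null(names(pro_pre))) as.numeric(pro_pre)
         else as.numeric(pro_pre[subset_names()])
  } else {
    f <- c(pro_pre, immature, mature_recirculating, transitional,
           splenic_mature)
  }
  if (length(f) != 5L || anyNA(f) || any(f < 0) || any(f > 1))
    bcd_error("survival fractions must be five values in [0, 1]",
              "bcd_invalid_input")
  structure(setNames(as.numeric(f), state_names()), class = "depletion_spec")
}

#' Apply an instantaneous depletion event
#'
#' @inheritParams population_derivatives
#' @param spec A [depletion_spec()].
#' @return The depleted [population_state()].
#' @export
apply_depletion <- function(state, spec = depletion_spec()) {
  validate_state(state)
  if (!inherits(spec, "depletion_spec")) spec <- depletion_spec(spec)
  population_state(setNames(as.numeric(state) * as.numeric(spec),
                            state_names()))
}

#' Mean residence time in a compartment
#'
#' The reciprocal of the compartment's summed death and exit rates, in 6-h
#' units: immature \eqn{1/(\mu_i+\delta_{i\_t}+\delta_{i\_re}+\delta_r)},
#' transitional \eqn{1/(\mu_t+\delta_t)}, BM mature recirculating
#' \eqn{1/(\mu_{re}+\phi_{BM})}, splenic mature \eqn{1/(\phi_s+\epsilon_{spl})}.
#'
#' @inheritParams population_derivatives
#' @param compartment One of `"immature"`, `"transitional"`,
#'   `"mature_recirculating"`, `"splenic_mature"`.
#' @return Residence time in 6-h units.
#' @examples
#' residence_time(default_params("depleted"), "immature")  # ~1.13
#' @export
residence_time <- function(params,
                           compartment = c("immature", "transitional",
                                           "mature_recirculating",
                                           "splenic_mature")) {
  validate_params(params)
  compartment <- match.arg(compartment)
  p <- as.list(unclass(params))
  total <- switch(compartment,
    immature = p$mu_i + p$delta_i_t + p$delta_i_re + p$delta_r,
    transitional = p$mu_t + p$delta_t,
    mature_recirculating = p$mu_re + p$phi_BM,
    splenic_mature = p$phi_s + p$eps_spl)
  if (total <= 0)
    bcd_error("total death + exit rate is zero: residence time undefined",
              "bcd_undefined_result")
  1 / total
}

#' Calibrate the source and carrying capacity to target totals
#'
#' The published parameter set omits the source `S` and carrying capacity
#' `K`. Given the 12 rate constants, a splenic-mature anchor total and the
#' desired logistic occupancy at steady state, this solves the steady-state
#' balance equations exactly: the immature, transitional, BM-mature and
#' splenic-mature balances determine the remaining four totals from the
#' anchor, then \eqn{K = (B_{oe}+B_{Mrec})/\mathrm{occupancy}^{*}} with
#' \eqn{\mathrm{occupancy}^{*}} chosen so the logistic term equals
#' `1 - occupancy`, and `S` closes the pro-/pre-B balance. If `target_totals`
#' is supplied, its `B_Mspl` entry is used as the anchor (the other entries
#' are recomputed to the nearest exactly-consistent point).
#'
#' @param rates Named vector of the 12 rate constants (see [rate_names()]).
#' @param target_totals Optional [population_state()]; only its splenic
#'   mature total is binding.
#' @param anchor_Mspl Splenic mature steady-state total (cells) used when
#'   `target_totals` is not given.
#' @param occupancy Steady-state occupancy \eqn{(B_{oe}+B_{Mrec})/K}, in
#'   (0, 1); the logistic proliferation factor at steady state is
#'   `1 - occupancy`.
#' @return List with elements `params` (full [kinetic_params()]), `S`, `K`,
#'   and `totals` (the exactly consistent steady-state [population_state()]).
#'   Signals `bcd_infeasible_target` if the implied source is negative.
#' @export
calibrate_source_and_capacity <- function(rates, target_totals = NULL,
                                          anchor_Mspl = 2e7,
                                          occupancy = 0.5) {
  r <- unlist(rates)
  missing <- setdiff(rate_names(), names(r))
  if (length(missing))
    bcd_error(paste0("missing rate(s): ", paste(missing, collapse = ", ")),
              "bcd_invalid_input")
  r <- as.list(r[rate_names()])
  if (any(unlist(r) < 0))
    bcd_error("rates must be non-negative", "bcd_invalid_input")
  if (occupancy <= 0 || occupancy >= 1)
    bcd_error("occupancy must be in (0, 1)", "bcd_invalid_input")
  if (!is.null(target_totals)) anchor_Mspl <- target_totals[["B_Mspl"]]
  if (!is.finite(anchor_Mspl) || anchor_Mspl <= 0)
    bcd_error("anchor splenic mature total must be positive",
              "bcd_invalid_input")

  # B_t = ct * B_i from the transitional balance; then the BM-mature and
  # splenic-mature balances are linear in (B_i, B_Mrec) given the anchor
  ct <- r$delta_i_t / (r$mu_t + r$delta_t)
  A <- rbind(c(r$delta_i_re, -(r$mu_re + r$phi_BM)),
             c(r$delta_t * ct, r$phi_BM))
  b <- c(-r$phi_s * anchor_Mspl, (r$phi_s + r$eps_spl) * anchor_Mspl)
  sol <- solve(A, b)
  B_i <- sol[1L]; B_Mrec <- sol[2L]
  if (B_i <= 0 || B_Mrec <= 0)
    bcd_error("rates imply non-positive steady-state totals",
              "bcd_infeasible_target")
  B_t <- ct * B_i
  out_i <- r$mu_i + r$delta_i_t + r$delta_r + r$delta_i_re
  B_oe <- B_i * out_i / r$delta_oe
  K <- (B_oe + B_Mrec) / occupancy
  lambda <- 1 - occupancy
  S <- r$delta_oe * B_oe - r$gamma * lambda * B_oe - r$delta_r * B_i
  if (S < 0)
    bcd_error(sprintf(
      "implied source is negative (S = %.3g): proliferation exceeds differentiation at the target",
      S), "bcd_infeasible_target")
  totals <- population_state(B_oe, B_i, B_Mrec, B_t, anchor_Mspl)
  params <- kinetic_params(c(unlist(r), S = S, K = K))
  attr(params, "totals") <- totals
  list(params = params, S = S, K = K, totals = totals)
}
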