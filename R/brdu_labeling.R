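#' @name brdu_labeling
#' @title Labeled/unlabeled dynamics under continuous BrdU administration
#'
#' @description
#' Each compartment is split into unlabeled (`UB_*`) and labeled (`LB_*`)
#' pools. Continuous BrdU administration marks every cell that divides: an
#' unlabeled pro-/pre-B cell that divides leaves the unlabeled pool and
#' contributes two labeled daughters, so the labeled pool gains
#' \eqn{\gamma\lambda(2\,UB_{oe} + LB_{oe})} while the unlabeled pool loses
#' \eqn{\gamma\lambda\,UB_{oe}}. All differentiation, flow and death terms
#' act identically on both pools (BrdU toxicity is neglected) and the source
#' `S` enters the unlabeled pool only (source cells are never labeled).
#' Summing the two pools recovers the totals model exactly.
NULL

#' Units per day on the 6-h clock
#' @param days Numeric vector of days.
#' @return Time in 6-h units.
#' @export
days_to_units <- function(days) 4 * days

lstate_names <- function() {
  c(paste0("U", state_names()), paste0("L", state_names()))
}

#' Per-pool rates of change of the labeled/unlabeled system
#'
#' Pure-R evaluation of the ten-equation right-hand side (the integrator
#' uses an equivalent compiled version).
#'
#' @param lstate Named numeric vector of length 10: unlabeled pools
#'   `UB_oe, UB_i, UB_Mrec, UB_t, UB_Mspl` then labeled pools `LB_*`.
#' @param params A [kinetic_params()] set.
#' @return Named numeric vector of the ten derivatives (cells per 6 h).
#' @export
labeling_derivatives <- function(lstate, params) {
  validate_params(params)
  if (length(lstate) != 10L || anyNA(lstate) || any(lstate < 0))
    bcd_error("labeled state must hold ten non-negative counts",
              "bcd_invalid_input")
  U <- as.numeric(lstate[1:5]); L <- as.numeric(lstate[6:10])
  p <- as.list(unclass(params))
  lam <- 1 - (U[1] + L[1] + U[3] + L[3]) / p$K
  out_i <- p$mu_i + p$delta_i_t + p$delta_r + p$delta_i_re
  flow <- function(X) {
    c(-p$delta_oe * X[1] + p$delta_r * X[2],
      p$delta_oe * X[1] - out_i * X[2],
      p$delta_i_re * X[2] + p$phi_s * X[5] - (p$mu_re + p$phi_BM) * X[3],
      p$delta_i_t * X[2] - (p$mu_t + p$delta_t) * X[4],
      p$delta_t * X[4] + p$phi_BM * X[3] - (p$phi_s + p$eps_spl) * X[5])
  }
  dU <- flow(U); dL <- flow(L)
  dU[1] <- dU[1] + p$S - p$gamma * lam * U[1]
  dL[1] <- dL[1] + p$gamma * lam * (2 * U[1] + L[1])
  setNames(c(dU, dL), lstate_names())
}

#' Experiment design for a labeling protocol
#'
#' @param group `"control"` or `"depleted"`.
#' @param depletion A [depletion_spec()]; used only for the depleted group.
#' @param recovery Interval between depletion and labeling start, 6-h units
#'   (default 136 = 34 days).
#' @param labeling_duration Continuous-labeling duration, 6-h units (default
#'   28 = 7 days).
#' @param measurement_days Days (from labeling start) at which labeled
#'   fractions are read out.
#' @param subsets Measured subsets (see [measured_subsets()]).
#' @return List with class `experiment_design`.
#' @export
experiment_design <- function(group = c("control", "depleted"),
                              depletion = depletion_spec(),
                              recovery = 136, labeling_duration = 28,
                              measurement_days = c(2, 4, 7),
                              subsets = measured_subsets()) {
  group <- match.arg(group)
  if (labeling_duration < 0 || recovery < 0)
    bcd_error("durations must be non-negative", "bcd_invalid_input")
  if (any(days_to_units(measurement_days) > labeling_duration))
    bcd_error("measurement days must fall within the labeling duration",
              "bcd_invalid_input")
  subset_index(subsets)
  if (group == "depleted" && is.null(depletion))
    bcd_error("depleted design requires a depletion spec", "bcd_invalid_input")
  structure(list(group = group, depletion = depletion, recovery = recovery,
                 labeling_duration = labeling_duration,
                 measurement_days = sort(measurement_days),
                 subsets = subsets),
            class = "experiment_design")
}

# time grid for the labeling phase: quarter-unit resolution plus the exact
# measurement times
label_grid <- function(design) {
  sort(unique(c(seq(0, design$labeling_duration, by = 0.25),
                days_to_units(design$measurement_days),
                design$labeling_duration)))
}

# state at labeling start for a design (steady state, plus depletion and
# recovery for the depleted protocol); ss may be precomputed
label_start_state <- function(params, design, opts, ss = NULL) {
  if (is.null(ss)) ss <- find_steady_state(params, opts)
  if (design$group == "control") return(list(ss = ss, start = ss))
  y <- apply_depletion(ss, design$depletion)
  if (design$recovery > 0) {
    out <- .ode(setNames(as.numeric(y), state_names()),
                c(0, design$recovery), "bcd_derivs_pop", params, opts)
    y <- population_state(pmax(as.numeric(out[nrow(out), -1L]), 0))
  }
  list(ss = ss, start = y)
}

#' Simulate a continuous-labeling experiment
#'
#' Control protocol: integrate the totals model from the all-zero state to
#' steady state, then start labeling with every pool unlabeled. Depleted
#' protocol: reach steady state, apply the depletion operator, integrate the
#' recovery interval, then start labeling.
#'
#' @inheritParams labeling_derivatives
#' @param design An [experiment_design()].
#' @param opts [steady_state_options()].
#' @return A `labeling_trajectory`: list with `time` (6-h units from labeling
#'   start), matrices `unlabeled`, `labeled`, `total` (columns = state
#'   names), `fraction` (labeled fractions, `NA` where a compartment is
#'   empty), plus `steady_state`, `start_state`, `design` and `params`.
#' @export
simulate_experiment <- function(params, design,
                                opts = steady_state_options()) {
  validate_params(params)
  if (!inherits(design, "experiment_design"))
    bcd_error("`design` must be an experiment_design", "bcd_invalid_input")
  init <- label_start_state(params, design, opts)
  times <- label_grid(design)
  y0 <- setNames(c(as.numeric(init$start), numeric(5L)), lstate_names())
  if (design$labeling_duration == 0) {
    sol <- matrix(y0, nrow = 1L, dimnames = list(NULL, lstate_names()))
    times <- 0
  } else {
    out <- .ode(y0, times, "bcd_derivs_brdu", params, opts)
    sol <- pmax(out[, -1L, drop = FALSE], 0)
  }
  U <- sol[, 1:5, drop = FALSE]; L <- sol[, 6:10, drop = FALSE]
  colnames(U) <- colnames(L) <- state_names()
  tot <- U + L
  frac <- L / tot
  frac[tot == 0] <- NA_real_
  structure(list(time = times, unlabeled = U, labeled = L, total = tot,
                 fraction = frac, steady_state = init$ss,
                 start_state = init$start, design = design, params = params),
            class = "labeling_trajectory")
}

#' Labeled fractions at measurement days
#'
#' @param traj A `labeling_trajectory` from [simulate_experiment()].
#' @param days Days (from labeling start) to report; must lie on the
#'   trajectory grid.
#' @param subsets Subsets to report.
#' @return Data frame with columns `day`, `subset`, `labeled_fraction`
#'   (`NA` marks an empty compartment).
#' @export
labeled_fraction_table <- function(traj, days = traj$design$measurement_days,
                                   subsets = traj$design$subsets) {
  if (!inherits(traj, "labeling_trajectory"))
    bcd_error("`traj` must be a labeling_trajectory", "bcd_invalid_input")
  idx <- match(days_to_units(days), traj$time)
  if (anyNA(idx))
    bcd_error("requested day(s) outside the trajectory grid",
              "bcd_invalid_input")
  cols <- subset_index(subsets)
  df <- expand.grid(subset = subsets, day = days, stringsAsFactors = FALSE,
                    KEEP.OUT.ATTRS = FALSE)[, 2:1]
  df$labeled_fraction <- as.vector(t(traj$fraction[idx, cols, drop = FALSE]))
  df
}

# fast path for inference: labeled fractions only at the measurement days,
# coarse grid, optionally reusing a precomputed steady state
predict_fractions <- function(params, design, opts = steady_state_options(),
                              ss = NULL) {
  init <- label_start_state(params, design, opts, ss = ss)
  tm <- days_to_units(design$measurement_days)
  times <- sort(unique(c(0, tm)))
  y0 <- setNames(c(as.numeric(init$start), numeric(5L)), lstate_names())
  out <- .ode(y0, times, "bcd_derivs_brdu", params, opts)
  sol <- pmax(out[match(tm, times), -1L, drop = FALSE], 0)
  U <- sol[, 1:5, drop = FALSE]; L <- sol[, 6:10, drop = FALSE]
  tot <- U + L
  frac <- L / tot
  frac[tot == 0] <- NA_real_
  frac <- frac[, subset_index(design$subsets), drop = FALSE]
  dimnames(frac) <- list(design$measurement_days, design$subsets)
  frac
}
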