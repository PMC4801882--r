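#' @name synthetic_data
#' @title Synthetic measurement cohorts
#'
#' @description
#' Generates per-mouse labeled-fraction tables with the statistical
#' structure the fitting stage assumes: cross-sectional mice (BrdU harvests
#' are terminal, so each measurement day uses fresh animals), Gaussian
#' observation noise on fractions clipped to \[0, 1\], and the study design
#' of two groups, measurement days 2/4/7 and eight mice per time point.
NULL

#' Specification of a synthetic cohort
#'
#' @param params Named list of [kinetic_params()] per group, e.g.
#'   `list(control = ..., depleted = ...)`; defaults to the published
#'   best-fit rates completed by calibration.
#' @param designs Named list of [experiment_design()] per group.
#' @param n_mice Mice per time point per group.
#' @param sd Gaussian noise standard deviation on labeled fractions.
#' @param seed Integer seed.
#' @return List with class `cohort_spec`.
#' @export
cohort_spec <- function(params = list(control = default_params("control"),
                                      depleted = default_params("depleted")),
                        designs = list(control = experiment_design("control"),
                                       depleted = experiment_design("depleted")),
                        n_mice = 8, sd = 0.03, seed) {
  if (n_mice < 1) bcd_error("need at least one mouse", "bcd_invalid_input")
  if (sd < 0) bcd_error("sd must be non-negative", "bcd_invalid_input")
  if (!setequal(names(params), names(designs)))
    bcd_error("`params` and `designs` must cover the same groups",
              "bcd_invalid_input")
  structure(list(params = params, designs = designs, n_mice = n_mice,
                 sd = sd, seed = seed), class = "cohort_spec")
}

#' Generate a synthetic measurement table
#'
#' Simulates each group's true labeling trajectory, then draws per-mouse
#' observations `clip(prediction + noise, 0, 1)` for every (day, subset,
#' mouse) combination. Mouse identifiers are distinct across days
#' (cross-sectional sampling). Deterministic given the spec's seed. A
#' message reports clipping when more than 1\% of rows hit the \[0, 1\]
#' bounds.
#'
#' @param spec A [cohort_spec()].
#' @param opts [steady_state_options()].
#' @return Measurement table: data frame with columns `mouse_id`, `group`,
#'   `day`, `subset`, `labeled_fraction`, and attribute `"clipped"` (number
#'   of clipped rows).
#' @export
generate_cohort <- function(spec, opts = steady_state_options()) {
  if (!inherits(spec, "cohort_spec"))
    bcd_error("`spec` must be a cohort_spec", "bcd_invalid_input")
  groups <- names(spec$params)
  preds <- lapply(groups, function(g)
    predict_fractions(spec$params[[g]], spec$designs[[g]], opts))
  names(preds) <- groups
  rows <- do.call(rbind, lapply(groups, function(g) {
    design <- spec$designs[[g]]
    do.call(rbind, lapply(design$measurement_days, function(d) {
      expand.grid(mouse = seq_len(spec$n_mice), subset = design$subsets,
                  KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE) |>
        transform(group = g, day = d,
                  mouse_id = sprintf("%s_d%g_m%02d", g, d,
                                     seq_len(spec$n_mice)))
    }))
  }))
  mu <- mapply(function(g, d, s) preds[[g]][as.character(d), s],
               rows$group, rows$day, rows$subset)
  raw <- with_seed(spec$seed, mu + rnorm(length(mu), sd = spec$sd))
  clipped <- sum(raw < 0 | raw > 1)
  if (clipped > 0.01 * length(raw))
    message(sprintf("%d of %d rows clipped to [0, 1]", clipped, length(raw)))
  out <- data.frame(mouse_id = rows$mouse_id, group = rows$group,
                    day = rows$day, subset = rows$subset,
                    labeled_fraction = pmin(pmax(raw, 0), 1))
  out <- out[order(out$group, out$day, out$subset, out$mouse_id), ]
  rownames(out) <- NULL
  attr(out, "clipped") <- clipped
  out
}

#' Steady-state total ranges around a parameter set
#'
#' Builds the totals-range table used by [steady_state_filter()]:
#' `totals * (1 - width)` to `totals * (1 + width)` per subset, from the
#' steady state of `params`. Stands in for the unpublished experimental
#' ranges of total cell numbers.
#'
#' @param params A [kinetic_params()] set (the "true" or control set).
#' @param relative_width Half-width as a fraction of the totals.
#' @param subsets Which subsets to constrain (default: all five).
#' @param opts [steady_state_options()].
#' @return Data frame with columns `subset`, `lower`, `upper`.
#' @export
generate_totals_ranges <- function(params, relative_width = 0.5,
                                   subsets = subset_names(),
                                   opts = steady_state_options()) {
  if (relative_width <= 0)
    bcd_error("relative width must be positive", "bcd_invalid_input")
  ss <- as.numeric(find_steady_state(params, opts))[subset_index(subsets)]
  data.frame(subset = subsets,
             lower = ss * (1 - relative_width),
             upper = ss * (1 + relative_width))
}
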