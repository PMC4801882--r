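#' @name parameters
#' @title Kinetic parameters and population states
#'
#' @description
#' The model is parameterized by 14 constants, all in units of "per 6 h"
#' (rates) or cells (`S`, `K`): the source inflow `S` into the pro-/pre-B
#' compartment, the maximum pro-/pre-B proliferation rate `gamma`, the
#' carrying capacity `K` shared by the pro-/pre-B and BM mature recirculating
#' compartments, the differentiation rates `delta_oe` (pro-/pre-B to
#' immature), `delta_r` (immature reflux back to pro-/pre-B), `delta_i_t`
#' (immature to transitional), `delta_i_re` (immature to BM mature) and
#' `delta_t` (transitional to splenic mature), the death rates `mu_i`,
#' `mu_re`, `mu_t`, the exchange flows `phi_BM` (BM mature to splenic mature)
#' and `phi_s` (splenic mature to BM mature), and the splenic-mature exit
#' rate `eps_spl`.
NULL

#' Canonical parameter and compartment names
#'
#' @return Character vectors: `param_names()` the 14 parameter keys in
#'   canonical order; `rate_names()` the 12 rate parameters (excluding the
#'   source `S` and capacity `K`); `state_names()` the five compartments in
#'   state order; `subset_names()` the five compartments in the measurement
#'   vocabulary; `measured_subsets()` the four subsets read out by flow
#'   cytometry in the BrdU experiment.
#' @export
param_names <- function() {
  c("S", "gamma", "K", "delta_oe", "delta_r", "mu_i", "delta_i_t",
    "delta_i_re", "mu_re", "phi_BM", "mu_t", "delta_t", "phi_s", "eps_spl")
}

#' @rdname param_names
#' @export
rate_names <- function() setdiff(param_names(), c("S", "K"))

#' @rdname param_names
#' @export
state_names <- function() c("B_oe", "B_i", "B_Mrec", "B_t", "B_Mspl")

#' @rdname param_names
#' @export
subset_names <- function() {
  c("pro_pre", "immature", "mature_recirculating", "transitional",
    "splenic_mature")
}

#' @rdname param_names
#' @export
measured_subsets <- function() subset_names()[-1L]

# subset vocabulary -> state index
subset_index <- function(subset) {
  idx <- match(subset, subset_names())
  if (anyNA(idx))
    bcd_error(paste0("unknown subset(s): ",
                     paste(subset[is.na(idx)], collapse = ", ")),
              "bcd_invalid_input")
  idx
}

#' Construct a kinetic parameter set
#'
#' @param ... Named parameter values (see [param_names()]), or a single named
#'   numeric vector / list containing them.
#' @param validate Check invariants (all finite and non-negative, `K > 0`).
#' @return A named numeric vector of length 14 with class `kinetic_params`.
#' @examples
#' p <- kinetic_params(S = 1e5, gamma = 0.3, K = 3e6, delta_oe = 0.5,
#'   delta_r = 0, mu_i = 0.1, delta_i_t = 0.6, delta_i_re = 0.19,
#'   mu_re = 0.008, phi_BM = 0.94, mu_t = 0.03, delta_t = 0.03,
#'   phi_s = 0.03, eps_spl = 0.008)
#' @export
kinetic_params <- function(..., validate = TRUE) {
  dots <- list(...)
  if (length(dots) == 1L && is.null(names(dots)) &&
      (is.numeric(dots[[1L]]) || is.list(dots[[1L]])))
    dots <- as.list(dots[[1L]])
  vals <- unlist(dots)
  missing <- setdiff(param_names(), names(vals))
  if (length(missing))
    bcd_error(paste0("missing parameter(s): ", paste(missing, collapse = ", ")),
              "bcd_invalid_input")
  extra <- setdiff(names(vals), param_names())
  if (length(extra))
    bcd_error(paste0("unknown parameter(s): ", paste(extra, collapse = ", ")),
              "bcd_invalid_input")
  p <- structure(as.numeric(vals[param_names()]), names = param_names(),
                 class = "kinetic_params")
  if (validate) validate_params(p)
  p
}

#' @rdname kinetic_params
#' @param p A `kinetic_params` object or named numeric vector.
#' @export
validate_params <- function(p) {
  v <- unclass(p)[param_names()]
  if (anyNA(v) || any(!is.finite(v)))
    bcd_error("all parameters must be finite", "bcd_invalid_input")
  if (any(v < 0))
    bcd_error("all parameters must be non-negative", "bcd_invalid_input")
  if (v[["K"]] <= 0)
    bcd_error("carrying capacity K must be positive", "bcd_invalid_input")
  invisible(p)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("<kinetic_params> (rates per 6 h, S in cells/6 h, K in cells)\n")
  print(signif(setNames(as.numeric(x), names(x)), 4))
  invisible(x)
}

#' Construct a population state
#'
#' Cell counts in the five compartments: pro-/pre-B (`B_oe`), immature
#' (`B_i`), BM mature recirculating (`B_Mrec`), transitional (`B_t`) and
#' splenic mature (`B_Mspl`).
#'
#' @param B_oe,B_i,B_Mrec,B_t,B_Mspl Non-negative cell counts, or a single
#'   named vector as `B_oe`.
#' @return Named numeric vector of length 5 with class `population_state`.
#' @export
population_state <- function(B_oe = 0, B_i = 0, B_Mrec = 0, B_t = 0,
                             B_Mspl = 0) {
  if (length(B_oe) == 5L) {
    s <- if (is.null(names(B_oe))) as.numeric(B_oe)
         else as.numeric(B_oe[state_names()])
  } else {
    s <- c(B_oe, B_i, B_Mrec, B_t, B_Mspl)
  }
  s <- structure(s, names = state_names(), class = "population_state")
  validate_state(s)
  s
}

validate_state <- function(s) {
  if (length(s) != 5L || anyNA(s) || any(!is.finite(s)))
    bcd_error("state must hold five finite cell counts", "bcd_invalid_input")
  if (any(s < 0))
    bcd_error("cell counts must be non-negative", "bcd_invalid_input")
  invisible(s)
}

#' Published best-fit rates and confidence intervals
#'
#' Bundled fixtures holding the published best-fit rate constants and their
#' 95\% profile-likelihood confidence intervals for control and depleted
#' mice. The source `S` and capacity `K` are not part of the published set;
#' see [calibrate_source_and_capacity()] and [default_params()].
#'
#' @param group `"control"` or `"depleted"`.
#' @return `table1_rates()`: a named numeric vector of the 12 rate constants
#'   (including the reflux rate `delta_r`, fixed at its default 0).
#'   `table1_ci()`: a data frame with columns `parameter`, `lower`, `upper`.
#' @export
table1_rates <- function(group = c("control", "depleted")) {
  group <- match.arg(group)
  path <- system.file("extdata", paste0("table1_", group, "_bestfit.yaml"),
                      package = "bcelldyn", mustWork = TRUE)
  v <- unlist(yaml::read_yaml(path))
  structure(as.numeric(v[rate_names()]), names = rate_names())
}

#' @rdname table1_rates
#' @export
table1_ci <- function(group = c("control", "depleted")) {
  group <- match.arg(group)
  path <- system.file("extdata", paste0("table1_", group, "_ci.csv"),
                      package = "bcelldyn", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Default full parameter set for a mouse group
#'
#' Completes the published rate constants with the unpublished source `S`
#' and carrying capacity `K` by calibrating the steady state to the default
#' subset totals (splenic-mature anchor and logistic occupancy; see
#' [calibrate_source_and_capacity()]).
#'
#' @inheritParams table1_rates
#' @param anchor_Mspl Target splenic mature steady-state total (cells).
#' @param occupancy Logistic occupancy \eqn{(B_{oe}+B_{Mrec})/K} at steady
#'   state, in (0, 1).
#' @return A [kinetic_params()] object with attribute `"totals"` holding the
#'   calibration target [population_state()].
#' @export
default_params <- function(group = c("control", "depleted"),
                           anchor_Mspl = 2e7, occupancy = 0.5) {
  group <- match.arg(group)
  cal <- calibrate_source_and_capacity(table1_rates(group),
                                       anchor_Mspl = anchor_Mspl,
                                       occupancy = occupancy)
  cal$params
}

#' Read or write a flat parameter config (YAML or JSON)
#'
#' Flat key-value files using exactly the keys of [param_names()]; partial
#' files (e.g. rates only) are allowed when `complete = FALSE`.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param complete Require all 14 keys and validate.
#' @return A `kinetic_params` object (or a named numeric vector of the keys
#'   present when `complete = FALSE`).
#' @export
read_params_config <- function(path, complete = TRUE) {
  x <- read_config(path)
  v <- unlist(x)
  extra <- setdiff(names(v), param_names())
  if (length(extra))
    bcd_error(paste0("unknown parameter key(s): ",
                     paste(extra, collapse = ", ")), "bcd_invalid_input")
  if (complete) return(kinetic_params(v))
  structure(as.numeric(v), names = names(v))
}

#' @rdname read_params_config
#' @param params Named numeric vector of parameter values.
#' @export
write_params_config <- function(params, path) {
  write_config(as.list(unclass(params)), path)
  invisible(path)
}

read_config <- function(path) {
  if (!file.exists(path))
    bcd_error(paste0("config file not found: ", path), "bcd_io_error")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else bcd_error("config must be .yaml, .yml or .json", "bcd_invalid_input")
}

write_config <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(x, path)
  else if (ext == "json")
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else bcd_error("config must be .yaml, .yml or .json", "bcd_invalid_input")
  invisible(path)
}
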