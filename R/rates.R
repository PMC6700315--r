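#' Maximum protein synthesis rate from a kinetic trace
#'
#' Operationalises the "maximum rate of deGFP synthesis" a plate-reader
#' experiment reports: the largest least-squares slope of the mature-reporter
#' signal over a sliding window, after a burn-in that skips the initial
#' transient (regime I). Defaults use a 30-min window and a 30-min burn-in,
#' matching the 1-6 h extent of the steady-state regime.
#'
#' @param trace A data frame with columns `time_s` and `degfp_mat_nM`
#'   (e.g. from [simulate_kinetics()]), or `time_s`/`value_nM`.
#' @param window Window width, s.
#' @param burn_in Earliest window start, s.
#' @return Maximum slope, nM/s.
#' @examples
#' tr <- simulate_kinetics(txtl_params(P70 = 1), t_end = 4 * 3600)
#' max_synthesis_rate(tr)
#' @export
max_synthesis_rate <- function(trace, window = 1800, burn_in = 1800) {
  stopifnot(is.data.frame(trace), "time_s" %in% names(trace))
  ycol <- if ("degfp_mat_nM" %in% names(trace)) "degfp_mat_nM" else "value_nM"
  if (!ycol %in% names(trace)) {
    stop("trace needs a 'degfp_mat_nM' or 'value_nM' column", call. = FALSE)
  }
  t <- trace$time_s
  y <- trace[[ycol]]
  span <- max(t) - min(t)
  if (span < 2 * window) {
    stop("trace must cover at least twice the window width", call. = FALSE)
  }
  starts <- t[t >= burn_in & t <= max(t) - window]
  if (length(starts) == 0) starts <- min(t)
  slopes <- vapply(starts, function(s) {
    idx <- which(t >= s & t <= s + window)
    if (length(idx) < 2) return(NA_real_)
    tt <- t[idx] - mean(t[idx])
    sum(tt * y[idx]) / sum(tt^2)
  }, numeric(1))
  max(slopes, na.rm = TRUE)
}

#' Maximum synthesis rate as a function of plasmid concentration
#'
#' Builds the rate-versus-plasmid curve that characterises a construct: one
#' simulation (or analytic steady-state evaluation) per plasmid
#' concentration, with each point labelled `"linear"` while the rate per
#' plasmid stays within 10% of its low-concentration limit and `"saturated"`
#' once free ribosomes are depleted onto the mRNA and the rate stops growing
#' proportionally.
#'
#' @param params A [txtl_params()] object; its `P70` field is overridden by
#'   the grid.
#' @param plasmid_grid Sorted plasmid concentrations, nM (>= 2 points).
#' @param method `"ode"` (default): simulate each concentration and take the
#'   sliding-window slope via [max_synthesis_rate()]; `"steady_state"`: the
#'   analytic regime-II rate from [steady_state_rate()] (identical within
#'   integration error, much faster).
#' @param t_end,window Passed to the simulation route.
#' @param linear_tol Relative departure from proportionality at which a point
#'   stops being labelled linear.
#' @return A tibble of class `txtl_rate_curve` with columns `plasmid_nM`,
#'   `max_rate_nM_per_s`, `regime`; the through-origin slope over the linear
#'   points is attached as attribute `"slope_linear"` (nM/s per nM).
#' @examples
#' rc <- rate_vs_plasmid(txtl_params(), c(0.5, 1, 2, 5, 10),
#'                       method = "steady_state")
#' rc
#' attr(rc, "slope_linear")
#' @export
rate_vs_plasmid <- function(params, plasmid_grid,
                            method = c("ode", "steady_state"),
                            t_end = 4 * 3600, window = 1800,
                            linear_tol = 0.1) {
  stopifnot(inherits(params, "txtl_params"))
  method <- match.arg(method)
  if (length(plasmid_grid) < 1 || is.unsorted(plasmid_grid)) {
    stop("plasmid_grid must be sorted and non-empty", call. = FALSE)
  }
  if (any(plasmid_grid < 0)) stop("plasmid concentrations must be >= 0",
                                  call. = FALSE)
  rates <- vapply(plasmid_grid, function(conc) {
    p <- set_params(params, P70 = conc)
    if (conc == 0) return(0)
    if (method == "ode") {
      tr <- simulate_kinetics(p, t_end = t_end)
      max_synthesis_rate(tr, window = window)
    } else {
      steady_state_rate(p)
    }
  }, numeric(1))
  out <- tibble::tibble(plasmid_nM = plasmid_grid,
                        max_rate_nM_per_s = rates)
  out$regime <- label_regimes(params, out$plasmid_nM, out$max_rate_nM_per_s,
                              linear_tol = linear_tol)
  lin <- out$regime == "linear" & out$plasmid_nM > 0
  slope <- if (any(lin)) {
    sum(out$max_rate_nM_per_s[lin] * out$plasmid_nM[lin]) /
      sum(out$plasmid_nM[lin]^2)
  } else {
    NA_real_
  }
  attr(out, "slope_linear") <- slope
  attr(out, "params") <- params
  attr(out, "method") <- method
  class(out) <- c("txtl_rate_curve", class(out))
  out
}

# label points linear while rate/plasmid stays within linear_tol of the
# low-concentration limit of the model (analytic, so labelling does not
# depend on which grid points happen to be present)
label_regimes <- function(params, plasmid, rates, linear_tol = 0.1) {
  ref <- low_conc_rate_per_plasmid(params)
  ratio <- ifelse(plasmid > 0, rates / plasmid, ref)
  ifelse(abs(ratio - ref) <= linear_tol * ref, "linear", "saturated")
}

# analytic limit of rate/plasmid as plasmid -> 0
low_conc_rate_per_plasmid <- function(params) {
  p0 <- set_params(params, P70 = 0)
  E0 <- solve_free_rnap(p0)$E0
  ktx <- transcription_rate_constant(params, E0)
  R_tot <- params$R_total
  ktx / kdeg_m(params) * params$kcat_p * R_tot / (params$KM_R + R_tot)
}
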