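scan_parameter_names <- function() {
  c("R_total", "E_total", "S70_total", "kdeg_m", "k_mat", "KM_70", "KM_R")
}

apply_scan_factor <- function(base, parameter, factor) {
  switch(parameter,
    kdeg_m = set_params(base, kd_m = base$kd_m * factor),  # KM_m held fixed
    do.call(set_params,
            c(list(base),
              stats::setNames(list(base[[parameter]] * factor), parameter)))
  )
}

#' One-at-a-time sensitivity scan on the rate-versus-plasmid curve
#'
#' Re-evaluates the rate curve with one biochemical constant scaled by each
#' of a set of factors (default one order of magnitude below to one above,
#' through 1/10, 1/3.33, 1, 3.33, 10) while all others stay at their
#' best-fit values. The effective mRNA degradation rate `kdeg_m` is scanned
#' by scaling `kd_m` with `KM_m` held fixed.
#'
#' @param base A [txtl_params()] object (the best fit).
#' @param parameter One of `"R_total"`, `"E_total"`, `"S70_total"`,
#'   `"kdeg_m"`, `"k_mat"`, `"KM_70"`, `"KM_R"`.
#' @param factors Multiplicative factors; must include 1 to anchor the
#'   reference curve.
#' @param plasmid_grid Plasmid concentrations, nM.
#' @param method Rate evaluation route, passed to [rate_vs_plasmid()];
#'   defaults to the analytic steady-state rate (note that the regime-II
#'   rate is exactly independent of `k_mat`, so a `k_mat` scan is flat under
#'   this method; use `method = "ode"` to expose finite-window maturation
#'   effects).
#' @return A tibble of class `txtl_sensitivity` in long format:
#'   `parameter`, `factor`, `plasmid_nM`, `max_rate_nM_per_s`. Per-factor
#'   summary metrics (maximum over the grid of the relative rate change
#'   versus the factor-1 curve) are attached as attribute `"summary"`.
#' @examples
#' sc <- sensitivity_scan(txtl_params(), "R_total",
#'                        plasmid_grid = c(1, 5, 10))
#' attr(sc, "summary")
#' @export
sensitivity_scan <- function(base, parameter,
                             factors = c(1 / 10, 1 / 3.33, 1, 3.33, 10),
                             plasmid_grid = c(0.5, 1, 2, 5, 10, 20, 30),
                             method = "steady_state") {
  stopifnot(inherits(base, "txtl_params"))
  if (!parameter %in% scan_parameter_names()) {
    stop("unknown scan parameter '", parameter, "'; must be one of: ",
         paste(scan_parameter_names(), collapse = ", "), call. = FALSE)
  }
  if (!1 %in% factors) factors <- sort(c(factors, 1))
  curves <- purrr::map(factors, function(f) {
    p <- apply_scan_factor(base, parameter, f)
    rc <- rate_vs_plasmid(p, plasmid_grid, method = method)
    tibble::tibble(parameter = parameter, factor = f,
                   plasmid_nM = rc$plasmid_nM,
                   max_rate_nM_per_s = rc$max_rate_nM_per_s)
  })
  out <- dplyr::bind_rows(curves)
  ref <- out$max_rate_nM_per_s[out$factor == 1]
  summary <- out |>
    dplyr::group_by(.data$factor) |>
    dplyr::summarise(
      max_rel_change = max(abs(.data$max_rate_nM_per_s - ref) /
                             pmax(ref, .Machine$double.eps)),
      .groups = "drop") |>
    dplyr::mutate(parameter = parameter, .before = 1)
  attr(out, "summary") <- summary
  attr(out, "summary_metric") <- max(summary$max_rel_change)
  class(out) <- c("txtl_sensitivity", class(out))
  out
}

#' Steady-state resource depletion versus plasmid concentration
#'
#' For each plasmid concentration, solves the polymerase conservation law,
#' takes the steady-state mRNA level, and solves the ribosome conservation
#' law at that level — giving the free polymerase `E0` and free ribosome
#' `R0` profiles whose sharp drops mark where transcription and translation
#' resources run out.
#'
#' @param base A [txtl_params()] object.
#' @param plasmid_grid Sorted plasmid concentrations, nM.
#' @return A tibble of class `txtl_depletion`: `plasmid_nM`, `mrna_ss_nM`,
#'   `E0_nM`, `E70_nM`, `Em_nM`, `R0_nM`, `Rm_nM`.
#' @export
resource_depletion_profile <- function(base, plasmid_grid) {
  stopifnot(inherits(base, "txtl_params"))
  if (is.unsorted(plasmid_grid)) stop("plasmid_grid must be sorted",
                                      call. = FALSE)
  rows <- purrr::map(plasmid_grid, function(conc) {
    p <- set_params(base, P70 = conc)
    e <- solve_free_rnap(p)
    m_ss <- if (conc == 0) 0 else {
      transcription_rate_constant(p, e$E0) / kdeg_m(p) * conc
    }
    r <- solve_free_ribosomes(p, m_ss)
    tibble::tibble(plasmid_nM = conc, mrna_ss_nM = m_ss,
                   E0_nM = e$E0, E70_nM = e$E70, Em_nM = e$Em,
                   R0_nM = r$R0, Rm_nM = r$Rm)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("txtl_depletion", class(out))
  out
}

#' Plasmid concentration at which ribosome demand saturates the pool
#'
#' Locates the plasmid concentration where the steady-state ribosome demand
#' `m_ss * beta` (with `beta = 1 + kcat_p * Lm / Cp`) crosses the total
#' ribosome pool — the model's predicted onset of the saturated regime.
#'
#' @param params A [txtl_params()] object.
#' @param interval Search interval for the crossing, nM plasmid.
#' @return Plasmid concentration, nM.
#' @examples
#' saturation_onset(txtl_params())  # ~5 nM for the best-fit construct
#' @export
saturation_onset <- function(params, interval = c(0.01, 100)) {
  stopifnot(inherits(params, "txtl_params"))
  beta <- ribosome_demand_factor(params)
  g <- function(conc) {
    p <- set_params(params, P70 = conc)
    e <- solve_free_rnap(p)
    q <- transcription_rate_constant(p, e$E0) * conc
    # past the degradation Vmax the mRNA pool grows without bound: demand
    # certainly exceeds the ribosome pool
    if (q >= p$kd_m) return(p$R_total)
    mrna_steady_state_mm(p, e$E0) * beta - params$R_total
  }
  stats::uniroot(g, interval, tol = 1e-6)$root
}
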