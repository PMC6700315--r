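#' Power law for the limiting DNA concentration
#'
#' Container for the load-calculator power law
#' `DNA_limit = prefactor * P^exp_P * U^exp_U * Lm^exp_Lm`, where `P` and
#' `U` are promoter and UTR strengths relative to the reference parts
#' (P70a, UTR1) and `Lm` the gene length in nt. The published fit is the
#' default: `250 * P^-0.987 * U^-0.352 * Lm^-0.583`.
#'
#' @param prefactor Prefactor, nM (absorbs the non-normalised gene length).
#' @param exp_P,exp_U,exp_Lm Exponents (all negative: more demand, lower
#'   limiting DNA).
#' @param residuals Optional per-sweep fit residuals.
#' @return An object of class `txtl_power_law`.
#' @export
txtl_power_law <- function(prefactor = 250, exp_P = -0.987,
                           exp_U = -0.352, exp_Lm = -0.583,
                           residuals = NULL) {
  stopifnot(prefactor > 0)
  if (any(c(exp_P, exp_U, exp_Lm) >= 0)) {
    stop("power-law exponents must be negative", call. = FALSE)
  }
  structure(list(prefactor = prefactor, exp_P = exp_P, exp_U = exp_U,
                 exp_Lm = exp_Lm, residuals = residuals),
            class = "txtl_power_law")
}

#' @export
print.txtl_power_law <- function(x, ...) {
  cat(sprintf(
    "<txtl_power_law> DNA_limit = %.4g * P^%.3f * U^%.3f * Lm^%.3f nM\n",
    x$prefactor, x$exp_P, x$exp_U, x$exp_Lm))
  invisible(x)
}

#' Tidy a limiting-DNA power law
#'
#' @param x A `txtl_power_law`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate`.
#' @export
tidy.txtl_power_law <- function(x, ...) {
  tibble::tibble(term = c("prefactor", "exp_P", "exp_U", "exp_Lm"),
                 estimate = c(x$prefactor, x$exp_P, x$exp_U, x$exp_Lm))
}

#' Limiting DNA concentration for one or more constructs
#'
#' Evaluates the load-calculator power law: the approximate plasmid
#' concentration above which translation resources (ribosomes) limit the
#' synthesis rate of the encoded protein.
#'
#' @param constructs Data frame with columns `P` (promoter strength relative
#'   to P70a), `U` (UTR strength relative to UTR1) and `Lm` (gene length,
#'   nt); one row per construct.
#' @param fit A [txtl_power_law()]; defaults to the published coefficients.
#' @return The input as a tibble with a `limiting_dna_nM` column appended.
#' @examples
#' limiting_dna(tibble::tibble(P = 1, U = 1, Lm = 800))  # ~5 nM
#' @export
limiting_dna <- function(constructs, fit = txtl_power_law()) {
  stopifnot(is.data.frame(constructs),
            all(c("P", "U", "Lm") %in% names(constructs)),
            inherits(fit, "txtl_power_law"))
  if (any(constructs$P <= 0) || any(constructs$U <= 0) ||
      any(constructs$Lm <= 0)) {
    stop("P, U and Lm must be strictly positive", call. = FALSE)
  }
  out <- tibble::as_tibble(constructs)
  out$limiting_dna_nM <- fit$prefactor *
    out$P^fit$exp_P * out$U^fit$exp_U * out$Lm^fit$exp_Lm
  out
}

# smallest plasmid concentration at which the model rate drops `departure`
# below the linear extrapolation from zero (the operational definition of
# "ribosomes become limiting")
find_limiting_conc <- function(params, departure = 0.1,
                               search_max = 300) {
  slope0 <- low_conc_rate_per_plasmid(params)
  g <- function(conc) {
    r <- suppressWarnings(steady_state_rate(set_params(params, P70 = conc)))
    r - (1 - departure) * slope0 * conc
  }
  lo <- 1e-3
  if (g(lo) <= 0) lo <- 1e-5
  hi <- lo * 2
  while (g(hi) > 0 && hi < search_max) hi <- hi * 2
  if (g(hi) > 0) {
    stop(sprintf(
      "rate never departs %.0f%% from linearity below %g nM plasmid",
      departure * 100, search_max), call. = FALSE)
  }
  stats::uniroot(g, c(lo, hi), tol = 1e-6)$root
}

#' Re-derive the limiting-DNA power law from the kinetic model
#'
#' Rebuilds the load-calculator equation from first principles: promoter
#' strength sweeps scale `kcat_m`, UTR strength sweeps scale `kcat_p`, and
#' gene-length sweeps vary `Lm` directly. For every swept value the model's
#' limiting DNA concentration is located (the plasmid concentration at which
#' the steady-state rate falls 10% below its linear extrapolation), a
#' log-log line is fitted per variable, and the three fits are combined.
#' The prefactor is normalised so that the reference construct
#' (`P = 1, U = 1, Lm = ref_Lm`) maps exactly onto the base model's own
#' limiting concentration.
#'
#' @param base A [txtl_params()] object (best-fit constants).
#' @param P_grid,U_grid Relative strength sweep grids (>= 5 points spanning
#'   >= 1 decade).
#' @param Lm_grid Gene length sweep grid, nt (same requirements).
#' @param ref_Lm Reference gene length for normalisation, nt.
#' @param departure Relative departure from linearity defining "limiting".
#' @return A [txtl_power_law()] with per-sweep residuals and the sweep data
#'   attached as attribute `"sweeps"`.
#' @export
derive_power_law <- function(base,
                             P_grid = 10^seq(-1, 0.4, length.out = 6),
                             U_grid = 10^seq(-1, 0.4, length.out = 6),
                             Lm_grid = round(10^seq(2.5, 3.9, length.out = 6)),
                             ref_Lm = 800,
                             departure = 0.1) {
  stopifnot(inherits(base, "txtl_params"))
  check_grid <- function(g, nm) {
    if (length(g) < 2) {
      stop("sweep grid for ", nm, " is underdetermined (need >= 2 points)",
           call. = FALSE)
    }
    if (length(g) < 5 || max(g) / min(g) < 10) {
      warning("sweep grid for ", nm,
              " should span >= 1 decade with >= 5 points", call. = FALSE)
    }
  }
  check_grid(P_grid, "P"); check_grid(U_grid, "U"); check_grid(Lm_grid, "Lm")
  ref <- set_params(base, Lm = ref_Lm)

  sweep_one <- function(grid, make_params) {
    lim <- vapply(grid, function(v) {
      find_limiting_conc(make_params(v), departure = departure)
    }, numeric(1))
    fit <- stats::lm(log(lim) ~ log(grid))
    list(exponent = unname(stats::coef(fit)[2]),
         rss = sum(stats::resid(fit)^2),
         data = tibble::tibble(value = grid, limiting_dna_nM = lim))
  }

  sw_P <- sweep_one(P_grid, function(s) set_params(ref, kcat_m = ref$kcat_m * s))
  sw_U <- sweep_one(U_grid, function(s) set_params(ref, kcat_p = ref$kcat_p * s))
  sw_L <- sweep_one(Lm_grid, function(L) set_params(base, Lm = L))

  d_ref <- find_limiting_conc(ref, departure = departure)
  prefactor <- d_ref / ref_Lm^sw_L$exponent

  fit <- txtl_power_law(
    prefactor = prefactor,
    exp_P = sw_P$exponent, exp_U = sw_U$exponent, exp_Lm = sw_L$exponent,
    residuals = c(P = sw_P$rss, U = sw_U$rss, Lm = sw_L$rss)
  )
  attr(fit, "sweeps") <- list(P = sw_P$data, U = sw_U$data, Lm = sw_L$data,
                              reference_limiting_nM = d_ref)
  fit
}

#' Ribosome load budget across multiple constructs
#'
#' When several DNA constructs share one TXTL reaction they compete for the
#' same ribosome pool. Each construct's load fraction is its planned
#' concentration over its own limiting DNA concentration; fractions add, and
#' each construct's usable limiting concentration shrinks by the load the
#' others impose.
#'
#' @param constructs Data frame with columns `P`, `U`, `Lm` and
#'   `planned_conc` (nM).
#' @param fit A [txtl_power_law()].
#' @return A tibble with per-construct `limiting_dna_nM`, `load_fraction`,
#'   and `remaining_limit_nM` (the construct's limiting concentration after
#'   discounting the load of all other constructs); the total load is
#'   attached as attribute `"total_load"`. A warning is raised when the
#'   total load reaches 1 (the calculator is approximate, so this is a
#'   caution, not an error).
#' @examples
#' budget_constructs(tibble::tibble(P = 1, U = 1, Lm = 800, planned_conc = 1))
#' @export
budget_constructs <- function(constructs, fit = txtl_power_law()) {
  stopifnot(is.data.frame(constructs),
            all(c("P", "U", "Lm", "planned_conc") %in% names(constructs)))
  if (nrow(constructs) == 0) stop("construct list is empty", call. = FALSE)
  if (any(constructs$planned_conc < 0)) {
    stop("planned_conc must be >= 0", call. = FALSE)
  }
  out <- limiting_dna(constructs, fit = fit)
  out$load_fraction <- out$planned_conc / out$limiting_dna_nM
  total <- sum(out$load_fraction)
  out$remaining_limit_nM <- out$limiting_dna_nM *
    pmax(1 - (total - out$load_fraction), 0)
  if (total >= 1) {
    warning(sprintf(
      "total ribosome load %.0f%% exceeds capacity: expression will be resource-limited",
      total * 100), call. = FALSE)
  }
  attr(out, "total_load") <- total
  out
}
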