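#' Right-hand side of the TXTL expression ODEs
#'
#' The model tracks three state variables: mRNA `m`, immature reporter
#' `deGFP_dark`, and fluorescent reporter `deGFP_mat`, all in nM.
#' Transcription is Michaelis-Menten in the holoenzyme, mRNA degradation
#' Michaelis-Menten in `m` (effectively first order since `KM_m >> m`),
#' translation Michaelis-Menten in free ribosomes, and maturation first
#' order. The free polymerase `E0` enters through the resource allocation;
#' the free ribosome pool must be consistent with the current `m`.
#'
#' @param state Named numeric vector with `m`, `deGFP_dark`, `deGFP_mat`, nM.
#' @param params A [txtl_params()] object.
#' @param E0 Free core RNA polymerase, nM (from [solve_free_rnap()]).
#' @param R0 Free ribosomes at the current mRNA level, nM (from
#'   [solve_free_ribosomes()]); recomputed from `state[["m"]]` when omitted.
#' @return Named numeric vector of time derivatives, nM/s.
#' @export
ode_rhs <- function(state, params, E0, R0 = NULL) {
  stopifnot(inherits(params, "txtl_params"))
  m <- state[["m"]]
  dark <- state[["deGFP_dark"]]
  if (is.null(R0)) R0 <- free_ribosomes(params, m)
  ktx <- transcription_rate_constant(params, E0)
  dm <- ktx * params$P70 - params$kd_m * m / (params$KM_m + m)
  ktl <- params$kcat_p * R0 / (params$KM_R + R0)
  ddark <- ktl * m - params$k_mat * dark
  dmat <- params$k_mat * dark
  c(m = dm, deGFP_dark = ddark, deGFP_mat = dmat)
}

# k_TX: effective transcription initiation frequency per promoter,
# kcat_m * E70 / (KM_70 + E70) rewritten in terms of E0
transcription_rate_constant <- function(params, E0) {
  params$kcat_m * E0 * params$S70_total /
    (params$KM_70 * (params$K70 + E0) + E0 * params$S70_total)
}

#' Simulate deGFP expression kinetics
#'
#' Integrates the three-variable model with the algebraic conservation laws
#' enforced at every right-hand-side evaluation: the free polymerase `E0` is
#' solved once per run (it depends only on constants and the plasmid
#' concentration), while the free ribosome pool `R0` is re-solved in closed
#' form at every call from the instantaneous mRNA level. Integration uses a
#' stiff-capable solver (`deSolve::lsoda`) at relative tolerance 1e-8 and
#' absolute tolerance 1e-9 nM, with output on a fixed grid mirroring
#' plate-reader sampling.
#'
#' @param params A [txtl_params()] object.
#' @param t_end End time, s.
#' @param t_step Output sampling interval, s (default 180 s, i.e. 3 min).
#' @param allocations If `TRUE` (default), include the resource partition
#'   (`E0`, `E70`, `Em`, `R0`, `Rm`) at every output time.
#' @return A tibble of class `txtl_trace` with columns `time_s`, `mrna_nM`,
#'   `degfp_dark_nM`, `degfp_mat_nM` and, when requested, the allocation
#'   columns. The parameter set is attached as attribute `"params"`.
#' @examples
#' tr <- simulate_kinetics(txtl_params(P70 = 1), t_end = 2 * 3600)
#' head(tr)
#' @export
simulate_kinetics <- function(params, t_end = 16 * 3600, t_step = 180,
                              allocations = TRUE) {
  stopifnot(inherits(params, "txtl_params"))
  if (t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (t_step <= 0 || t_step > t_end) {
    stop("t_step must be in (0, t_end]", call. = FALSE)
  }
  alloc_E <- solve_free_rnap(params)
  E0 <- alloc_E$E0
  times <- seq(0, t_end, by = t_step)
  if (times[length(times)] < t_end) times <- c(times, t_end)
  y0 <- c(m = 0, deGFP_dark = 0, deGFP_mat = 0)
  rhs <- function(t, y, parms) {
    list(ode_rhs(y, params, E0 = E0))
  }
  out <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = 1e-8, atol = 1e-9)
  if (!is.null(attr(out, "istate")) && attr(out, "istate")[1] < 0) {
    stop(sprintf("ODE integration failed near t = %.1f s",
                 out[nrow(out), "time"]), call. = FALSE)
  }
  out <- as.data.frame(out)
  # clip solver-level negative round-off
  out$m <- pmax(out$m, 0)
  out$deGFP_dark <- pmax(out$deGFP_dark, 0)
  out$deGFP_mat <- pmax(out$deGFP_mat, 0)
  check_mrna_vs_KM(params, max(out$m))
  tr <- tibble::tibble(
    time_s = out$time,
    mrna_nM = out$m,
    degfp_dark_nM = out$deGFP_dark,
    degfp_mat_nM = out$deGFP_mat
  )
  if (allocations) {
    rib <- solve_free_ribosomes(params, tr$mrna_nM)
    tr$E0_nM <- E0
    tr$E70_nM <- alloc_E$E70
    tr$Em_nM <- alloc_E$Em
    tr$R0_nM <- rib$R0
    tr$Rm_nM <- rib$Rm
  }
  attr(tr, "params") <- params
  class(tr) <- c("txtl_trace", class(tr))
  tr
}

#' Steady-state mRNA concentration
#'
#' In the steady state the mRNA level is set by the balance of synthesis and
#' first-order degradation: `m_ss = k_TX / kdeg_m * P70`, with the initiation
#' frequency `k_TX` evaluated from the solved free-polymerase level (or
#' approximated by `kcat_m` itself in the regime where the holoenzyme far
#' exceeds `KM_70`).
#'
#' @param params A [txtl_params()] object.
#' @param approximate If `TRUE`, use `k_TX = kcat_m` (the strong-promoter,
#'   polymerase-replete limit); if `FALSE` (default) evaluate `k_TX` at the
#'   solved `E0`.
#' @return Steady-state mRNA, nM.
#' @examples
#' mrna_steady_state(txtl_params(P70 = 1))
#' @export
mrna_steady_state <- function(params, approximate = FALSE) {
  stopifnot(inherits(params, "txtl_params"))
  if (params$P70 == 0) return(0)
  ktx <- if (approximate) {
    params$kcat_m
  } else {
    transcription_rate_constant(params, solve_free_rnap(params)$E0)
  }
  ktx / kdeg_m(params) * params$P70
}

# exact steady-state mRNA keeping the Michaelis-Menten degradation form:
# k_TX * P70 = kd_m * m / (KM_m + m)  =>  m = KM_m q / (kd_m - q)
mrna_steady_state_mm <- function(params, E0 = NULL) {
  if (params$P70 == 0) return(0)
  if (is.null(E0)) E0 <- solve_free_rnap(params)$E0
  q <- transcription_rate_constant(params, E0) * params$P70
  if (q >= params$kd_m) {
    stop("transcription outruns mRNA degradation capacity (kd_m); no steady state",
         call. = FALSE)
  }
  params$KM_m * q / (params$kd_m - q)
}

#' Linear-regime protein synthesis rate
#'
#' At low plasmid concentration the mature reporter accumulates linearly at
#' `kcat_p * kcat_m / kdeg_m * P70` (nM/s): transcription and translation
#' both run at their full rate constants and the mRNA pool sits at its
#' steady state.
#'
#' @param params A [txtl_params()] object.
#' @return Protein synthesis rate, nM/s.
#' @examples
#' linear_regime_protein_rate(txtl_params(P70 = 1))
#' @export
linear_regime_protein_rate <- function(params) {
  stopifnot(inherits(params, "txtl_params"))
  params$kcat_p * params$kcat_m / kdeg_m(params) * params$P70
}

#' Steady-state (regime II) protein synthesis rate from the full model
#'
#' Evaluates the regime-II rate of mature-reporter accumulation without
#' integrating the ODEs: the free polymerase is solved from its conservation
#' law, the steady-state mRNA from the synthesis/degradation balance
#' (Michaelis-Menten degradation form), the free ribosome pool from its
#' conservation law at that mRNA level, and the rate is
#' `kcat_p * m_ss * R0 / (KM_R + R0)`. This equals the late-time slope of a
#' simulated trace and captures both the linear and the ribosome-saturated
#' regime.
#'
#' @param params A [txtl_params()] object (vectorise over plasmid via
#'   `vapply` or [rate_vs_plasmid()]).
#' @return Synthesis rate, nM/s.
#' @export
steady_state_rate <- function(params) {
  stopifnot(inherits(params, "txtl_params"))
  if (params$P70 == 0) return(0)
  E0 <- solve_free_rnap(params)$E0
  q <- transcription_rate_constant(params, E0) * params$P70
  if (q >= params$kd_m) {
    # mRNA synthesis exceeds the degradation Vmax: no finite mRNA steady
    # state; translation flux approaches its ribosome-limited ceiling
    warning(paste0("transcription outruns mRNA degradation capacity; ",
                   "returning the ribosome-limited rate ceiling"),
            call. = FALSE)
    return(params$kcat_p * params$R_total / ribosome_demand_factor(params))
  }
  m_ss <- mrna_steady_state_mm(params, E0)
  R0 <- free_ribosomes(params, m_ss)
  params$kcat_p * m_ss * R0 / (params$KM_R + R0)
}
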