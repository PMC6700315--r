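#' Biochemical parameter set for the TXTL expression model
#'
#' Constructs and validates the full set of biochemical constants and
#' concentrations the model needs. All concentrations are in nM and all times
#' in seconds; rate constants are 1/s, elongation speeds nt/s. Defaults are
#' the best-fit constants for the reference construct (strong sigma-70
#' promoter P70a driving deGFP through the strong UTR1) in the all-E. coli
#' TXTL system.
#'
#' @param kcat_m Transcription rate constant (initiation), 1/s. Values above
#'   0.5/s exceed the physical limit of ~30 initiations per minute and
#'   trigger a warning.
#' @param KM_70 Michaelis constant of transcription with respect to the
#'   holoenzyme, nM.
#' @param K70 Dissociation constant of the sigma-70/core RNA polymerase
#'   complex, nM.
#' @param S70_total Total sigma factor 70, nM. The model output is insensitive
#'   to this value over the plausible 30-35 nM range.
#' @param E_total Total core RNA polymerase, nM.
#' @param kd_m Vmax of mRNA degradation (rate constant times RNase
#'   concentration), nM/s.
#' @param KM_m Michaelis constant of mRNA degradation, nM. Must be much larger
#'   than any simulated mRNA concentration so that degradation stays
#'   effectively first order with rate `kd_m/KM_m`; the Michaelis-Menten form
#'   is kept only to keep mRNA non-negative numerically.
#' @param kcat_p Translation rate constant (initiation), 1/s. Same 0.5/s
#'   ceiling as `kcat_m`.
#' @param KM_R Michaelis constant of translation with respect to free
#'   ribosomes, nM.
#' @param R_total Total active ribosomes, nM.
#' @param k_mat First-order maturation rate of the dark reporter into its
#'   fluorescent form, 1/s. The default 1.2e-3/s (~14 min characteristic
#'   time) is a documented placeholder in the right physiological range, not
#'   a published constant; fit it from a maturation assay with
#'   [fit_maturation()] when it matters.
#' @param Cm Transcription elongation speed, nt/s.
#' @param Cp Translation elongation speed, nt/s (the printed value 2.5 nt/s
#'   accompanies a stated 1 amino acid/s).
#' @param Lm Length of the transcribed/translated gene, nt.
#' @param P70 Promoter (= plasmid) concentration, nM. The only field allowed
#'   to be zero.
#'
#' @return A list of class `txtl_params`.
#' @seealso [read_params_json()], [write_params_json()], [simulate_kinetics()]
#' @examples
#' p <- txtl_params()            # best-fit reference parameters
#' txtl_params(P70 = 5)          # 5 nM plasmid
#' @export
txtl_params <- function(kcat_m = 6.5e-2,
                        KM_70 = 1,
                        K70 = 0.26,
                        S70_total = 30,
                        E_total = 400,
                        kd_m = 6.6,
                        KM_m = 8000,
                        kcat_p = 6e-3,
                        KM_R = 10,
                        R_total = 1100,
                        k_mat = 1.2e-3,
                        Cm = 10,
                        Cp = 2.5,
                        Lm = 750,
                        P70 = 1) {
  p <- list(
    kcat_m = kcat_m, KM_70 = KM_70, K70 = K70, S70_total = S70_total,
    E_total = E_total, kd_m = kd_m, KM_m = KM_m, kcat_p = kcat_p,
    KM_R = KM_R, R_total = R_total, k_mat = k_mat, Cm = Cm, Cp = Cp,
    Lm = Lm, P70 = P70
  )
  validate_txtl_params(p)
  structure(p, class = "txtl_params")
}

#' @export
print.txtl_params <- function(x, ...) {
  cat("<txtl_params> (nM, s)\n")
  df <- tibble::tibble(parameter = names(x),
                       value = vapply(x, as.numeric, numeric(1)))
  print(as.data.frame(df), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.txtl_params <- function(x, ...) {
  as.data.frame(tibble::as_tibble(unclass(x)))
}

txtl_param_names <- function() {
  c("kcat_m", "KM_70", "K70", "S70_total", "E_total", "kd_m", "KM_m",
    "kcat_p", "KM_R", "R_total", "k_mat", "Cm", "Cp", "Lm", "P70")
}

validate_txtl_params <- function(p) {
  nm <- txtl_param_names()
  missing <- setdiff(nm, names(p))
  if (length(missing) > 0) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in nm) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
    }
  }
  strict_pos <- setdiff(nm, "P70")
  bad <- strict_pos[vapply(strict_pos, function(f) p[[f]] <= 0, logical(1))]
  if (length(bad) > 0) {
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$P70 < 0) stop("P70 must be >= 0", call. = FALSE)
  if (p$kcat_m > 0.5) {
    warning("kcat_m = ", p$kcat_m,
            " /s exceeds the ~0.5/s physical cap on transcription initiation",
            call. = FALSE)
  }
  if (p$kcat_p > 0.5) {
    warning("kcat_p = ", p$kcat_p,
            " /s exceeds the ~0.5/s physical cap on translation initiation",
            call. = FALSE)
  }
  invisible(p)
}

# Effective first-order mRNA degradation rate kd_m/KM_m (1/s), valid when
# KM_m >> [m].
#' Effective first-order mRNA degradation rate
#'
#' Returns `kd_m / KM_m` (1/s), the first-order degradation rate the
#' Michaelis-Menten degradation term reduces to when the mRNA concentration
#' stays far below `KM_m`.
#'
#' @param params A [txtl_params()] object.
#' @return Degradation rate, 1/s.
#' @export
kdeg_m <- function(params) {
  stopifnot(inherits(params, "txtl_params"))
  params$kd_m / params$KM_m
}

# warn if a simulated mRNA level strains the KM_m >> [m] assumption
check_mrna_vs_KM <- function(params, m_max) {
  if (is.finite(m_max) && m_max > 0 && params$KM_m < 10 * m_max) {
    warning(sprintf(
      paste0("simulated mRNA reaches %.3g nM but KM_m = %.3g nM; the ",
             "first-order degradation assumption (KM_m >> [m]) is strained"),
      m_max, params$KM_m), call. = FALSE)
  }
  invisible(NULL)
}

#' Update fields of a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-running
#' validation.
#'
#' @param params A [txtl_params()] object.
#' @param ... Named parameter values to replace, e.g. `P70 = 5`.
#' @return A [txtl_params()] object.
#' @examples
#' set_params(txtl_params(), P70 = 5, R_total = 11000)
#' @export
set_params <- function(params, ...) {
  upd <- list(...)
  unknown <- setdiff(names(upd), txtl_param_names())
  if (length(unknown) > 0) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  p <- unclass(params)
  p[names(upd)] <- upd
  validate_txtl_params(p)
  structure(p, class = "txtl_params")
}
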