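#' Holoenzyme concentration at equilibrium
#'
#' Sigma-70 binding to free core RNA polymerase is treated as a fast
#' equilibrium with dissociation constant `K70`, so the holoenzyme
#' concentration is `E70 = E0 * S70_total / (K70 + E0)`.
#'
#' @param E0 Free core RNA polymerase, nM.
#' @param params A [txtl_params()] object.
#' @return Holoenzyme concentration E70, nM (bounded by `S70_total`).
#' @export
holoenzyme <- function(E0, params) {
  stopifnot(inherits(params, "txtl_params"))
  if (any(E0 < 0)) stop("E0 must be >= 0", call. = FALSE)
  E0 * params$S70_total / (params$K70 + E0)
}

# residual of the core-RNAP conservation law as a function of E0:
# E0 + E70(E0) + Em(E0) - E_total.  Strictly increasing in E0.
rnap_conservation_residual <- function(E0, params) {
  S70 <- params$S70_total
  K70 <- params$K70
  E70 <- E0 * S70 / (K70 + E0)
  alpha <- 1 + params$kcat_m * params$Lm / params$Cm
  Em <- E0 * S70 * params$P70 * alpha /
    (params$KM_70 * (K70 + E0) + E0 * S70)
  E0 + E70 + Em - params$E_total
}

#' Partition core RNA polymerase between free, holoenzyme, and DNA-engaged pools
#'
#' Solves the RNA polymerase conservation law for the free core enzyme `E0`:
#' total polymerase splits into free core enzyme, sigma-70 holoenzyme, and
#' polymerases engaged on the template (on the promoter plus elongating,
#' the latter scaling with the transit time `Lm/Cm`). The conservation
#' residual is strictly increasing in `E0` on `[0, E_total]`, so the
#' bracketed root is unique. Because the template concentration is constant,
#' `E0` does not depend on the mRNA level and is solved once per parameter
#' set.
#'
#' @param params A [txtl_params()] object.
#' @param tol Absolute tolerance on `E0`, nM.
#' @return A one-row tibble with columns `E0`, `E70`, `Em`, `S70_free`
#'   (all nM) and the conservation `residual`.
#' @examples
#' solve_free_rnap(txtl_params(P70 = 5))
#' @export
solve_free_rnap <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "txtl_params"))
  lo <- rnap_conservation_residual(0, params)
  hi <- rnap_conservation_residual(params$E_total, params)
  if (lo > 0 || hi < 0) {
    stop(sprintf(
      "no root of the RNAP conservation law in [0, %.6g] nM (residuals %.3g, %.3g)",
      params$E_total, lo, hi), call. = FALSE)
  }
  root <- stats::uniroot(rnap_conservation_residual, c(0, params$E_total),
                         params = params, tol = tol)
  E0 <- root$root
  E70 <- holoenzyme(E0, params)
  alpha <- 1 + params$kcat_m * params$Lm / params$Cm
  Em <- E0 * params$S70_total * params$P70 * alpha /
    (params$KM_70 * (params$K70 + E0) + E0 * params$S70_total)
  tibble::tibble(
    E0 = E0, E70 = E70, Em = Em,
    S70_free = params$S70_total - E70,
    residual = E0 + E70 + Em - params$E_total
  )
}

# coefficient multiplying [m] in the ribosome demand: one ribosome on the
# ribosome binding site plus kcat_p * Lm / Cp elongating.
ribosome_demand_factor <- function(params) {
  1 + params$kcat_p * params$Lm / params$Cp
}

#' Partition ribosomes between free and mRNA-engaged pools
#'
#' Solves the ribosome conservation law for the free ribosome concentration
#' `R0` at a given mRNA concentration. The law
#' `R_total = R0 + R0 * m / (KM_R + R0) * beta`, with
#' `beta = 1 + kcat_p * Lm / Cp`, rearranges to the quadratic
#' `R0^2 + R0 * (KM_R + m * beta - R_total) - KM_R * R_total = 0`,
#' whose unique positive root is evaluated in closed form (with a
#' cancellation-safe branch for large `m`).
#'
#' @param params A [txtl_params()] object.
#' @param m mRNA concentration(s), nM (vectorised).
#' @return A tibble with one row per `m`: columns `m`, `R0`, `Rm`, and the
#'   conservation `residual`.
#' @examples
#' solve_free_ribosomes(txtl_params(), m = c(0, 100, 400))
#' @export
solve_free_ribosomes <- function(params, m) {
  stopifnot(inherits(params, "txtl_params"))
  if (any(m < 0)) stop("m must be >= 0", call. = FALSE)
  R0 <- free_ribosomes(params, m)
  beta <- ribosome_demand_factor(params)
  Rm <- R0 * m / (params$KM_R + R0) * beta
  tibble::tibble(m = m, R0 = R0, Rm = Rm,
                 residual = R0 + Rm - params$R_total)
}

# closed-form positive root; numerically stable form avoiding subtraction of
# nearly equal quantities when b > 0 (large m)
free_ribosomes <- function(params, m) {
  beta <- ribosome_demand_factor(params)
  b <- params$KM_R + m * beta - params$R_total
  c0 <- -params$KM_R * params$R_total
  disc <- sqrt(b^2 - 4 * c0)
  ifelse(b <= 0, (-b + disc) / 2, -2 * c0 / (b + disc))
}
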