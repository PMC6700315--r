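#' Measurement noise model for synthetic plate-reader data
#'
#' Noise is multiplicative-plus-additive Gaussian, truncated at zero:
#' `y = max(0, x * (1 + e_m) + e_a)` with `e_m ~ N(0, multiplicative_sd)`
#' and `e_a ~ N(0, additive_sd)`. The multiplicative component models
#' well-to-well variability (pipetting, calibration, lysate batch) — the
#' dominant error plate-reader repeats show — so it is drawn once per well:
#' a whole kinetic trace shares one gain, while every point of a
#' rate-versus-plasmid curve (one well each) gets its own. The additive
#' component is per-point instrument jitter. Defaults (3% multiplicative,
#' 5 nM additive) are a documented convention for this instrument class;
#' the seed is mandatory so every generated dataset is reproducible.
#'
#' @param multiplicative_sd Fractional standard deviation (>= 0).
#' @param additive_sd Additive standard deviation, nM (>= 0).
#' @param seed Integer random seed.
#' @return An object of class `txtl_noise`.
#' @export
noise_model <- function(multiplicative_sd = 0.03, additive_sd = 5, seed) {
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  stopifnot(multiplicative_sd >= 0, additive_sd >= 0)
  structure(list(multiplicative_sd = multiplicative_sd,
                 additive_sd = additive_sd,
                 seed = as.integer(seed)),
            class = "txtl_noise")
}

apply_noise <- function(x, noise, gain = c("per_point", "per_trace")) {
  stopifnot(inherits(noise, "txtl_noise"))
  gain <- match.arg(gain)
  n <- length(x)
  g <- if (gain == "per_trace") {
    rep(stats::rnorm(1, 0, noise$multiplicative_sd), n)
  } else {
    stats::rnorm(n, 0, noise$multiplicative_sd)
  }
  y <- x * (1 + g) + stats::rnorm(n, 0, noise$additive_sd)
  pmax(y, 0)
}

#' Generate a noisy plate-reader kinetics run with known ground truth
#'
#' Simulates the expression model, samples the mature-reporter signal on a
#' plate-reader time grid (default every 3 min for 16 h), and applies
#' multiplicative then additive measurement noise. The noiseless simulated
#' trace is attached so recovery can be checked against ground truth.
#'
#' @param params A [txtl_params()] object.
#' @param noise A [noise_model()] (carries the seed).
#' @param interval Sampling interval, s.
#' @param duration Run duration, s.
#' @param well,condition Labels carried into the output.
#' @return A tibble of class `txtl_plate_run` with columns `time_s`, `well`,
#'   `condition`, `value_nM`; the noiseless trace is attribute `"truth"`,
#'   the parameters attribute `"params"`.
#' @export
generate_kinetics <- function(params, noise, interval = 180,
                              duration = 16 * 3600,
                              well = "A1", condition = "P70a-deGFP") {
  stopifnot(inherits(params, "txtl_params"), inherits(noise, "txtl_noise"))
  if (interval <= 0 || duration < interval) {
    stop("need interval > 0 and duration >= interval", call. = FALSE)
  }
  truth <- simulate_kinetics(params, t_end = duration, t_step = interval)
  set.seed(noise$seed)
  out <- tibble::tibble(
    time_s = truth$time_s,
    well = well,
    condition = condition,
    value_nM = apply_noise(truth$degfp_mat_nM, noise, gain = "per_trace")
  )
  attr(out, "truth") <- truth
  attr(out, "params") <- params
  attr(out, "noise") <- noise
  class(out) <- c("txtl_plate_run", class(out))
  out
}

#' Generate a noisy first-order decay trace
#'
#' Samples `A * exp(-k t)` on a plate-reader grid with measurement noise,
#' emulating an mRNA-lifetime assay.
#'
#' @param k Decay rate, 1/s.
#' @param A Initial amplitude, nM.
#' @param noise A [noise_model()].
#' @param interval Sampling interval, s.
#' @param duration Run duration, s.
#' @return A tibble with `time_s`, `signal_nM`; noiseless values as
#'   attribute `"truth"`.
#' @export
generate_decay_trace <- function(k, A, noise, interval = 180,
                                 duration = 2 * 3600) {
  stopifnot(k > 0, A > 0, inherits(noise, "txtl_noise"))
  times <- seq(0, duration, by = interval)
  truth <- A * exp(-k * times)
  set.seed(noise$seed)
  out <- tibble::tibble(time_s = times,
                        signal_nM = apply_noise(truth, noise,
                                                gain = "per_trace"))
  attr(out, "truth") <- tibble::tibble(time_s = times, signal_nM = truth)
  attr(out, "ground_truth") <- c(k = k, A = A)
  out
}

#' Generate a noisy maturation (saturating-rise) trace
#'
#' Samples `F_inf * (1 - exp(-k_mat t))` with measurement noise, emulating
#' the fluorescence rise after translation arrest used to fit the reporter
#' maturation rate.
#'
#' @param k_mat Maturation rate, 1/s.
#' @param F_inf Plateau fluorescence, nM.
#' @param noise A [noise_model()].
#' @param interval,duration Sampling grid, s.
#' @return A tibble with `time_s`, `signal_nM`; ground truth attached.
#' @export
generate_maturation_trace <- function(k_mat, F_inf, noise, interval = 180,
                                      duration = 2 * 3600) {
  stopifnot(k_mat > 0, F_inf > 0, inherits(noise, "txtl_noise"))
  times <- seq(0, duration, by = interval)
  truth <- F_inf * (1 - exp(-k_mat * times))
  set.seed(noise$seed)
  out <- tibble::tibble(time_s = times,
                        signal_nM = apply_noise(truth, noise,
                                                gain = "per_trace"))
  attr(out, "truth") <- tibble::tibble(time_s = times, signal_nM = truth)
  attr(out, "ground_truth") <- c(k_mat = k_mat, F_inf = F_inf)
  out
}

#' Generate rate curves for a promoter-by-UTR strength grid
#'
#' Emulates the nine-construct characterisation experiment: each promoter
#' strength scales `kcat_m`, each UTR strength scales `kcat_p`, and a
#' rate-versus-plasmid curve is produced per combination with measurement
#' noise on the rates. Default strengths span two orders of magnitude, so
#' the strongest pair saturates near its model-determined limiting
#' concentration while the weakest stays linear to 30 nM.
#'
#' @param noise A [noise_model()] (use `additive_sd = 0` unless your rate
#'   units warrant an absolute noise floor).
#' @param promoter_strengths,utr_strengths Named vectors of relative
#'   strengths (reference part = 1).
#' @param base_params A [txtl_params()] for the reference pair.
#' @param plasmid_grid Plasmid concentrations, nM.
#' @param method Rate evaluation route, see [rate_vs_plasmid()].
#' @return A long tibble: `plasmid_nM`, `max_rate_nM_per_s`, `promoter`,
#'   `utr`; the noiseless curves and generating strengths are attached as
#'   attribute `"truth"`.
#' @export
generate_nine_combo_dataset <- function(noise,
                                        promoter_strengths = c(P70a = 1,
                                                               P70b = 0.3,
                                                               P70c = 0.05),
                                        utr_strengths = c(UTR1 = 1,
                                                          UTR2 = 0.3,
                                                          UTR3 = 0.05),
                                        base_params = txtl_params(),
                                        plasmid_grid = c(0.5, 1, 2, 5,
                                                         10, 20, 30),
                                        method = "steady_state") {
  stopifnot(inherits(noise, "txtl_noise"),
            all(promoter_strengths > 0), all(utr_strengths > 0))
  grid <- tidyr::expand_grid(
    promoter = names(promoter_strengths),
    utr = names(utr_strengths)
  )
  clean <- purrr::pmap(grid, function(promoter, utr) {
    p <- set_params(base_params,
                    kcat_m = base_params$kcat_m *
                      promoter_strengths[[promoter]],
                    kcat_p = base_params$kcat_p * utr_strengths[[utr]])
    rc <- rate_vs_plasmid(p, plasmid_grid, method = method)
    tibble::tibble(plasmid_nM = rc$plasmid_nM,
                   max_rate_nM_per_s = rc$max_rate_nM_per_s,
                   regime = rc$regime,
                   promoter = promoter, utr = utr)
  }) |>
    dplyr::bind_rows()
  set.seed(noise$seed)
  out <- clean
  out$max_rate_nM_per_s <- apply_noise(clean$max_rate_nM_per_s, noise)
  out$regime <- NULL
  attr(out, "truth") <- list(curves = clean,
                             promoter_strengths = promoter_strengths,
                             utr_strengths = utr_strengths)
  out
}
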