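new_txtl_fit <- function(estimates, rss, converged, bounds = NULL,
                         model = "", note = NULL, n = NA_integer_) {
  structure(
    list(estimates = estimates, rss = rss, converged = converged,
         bounds = bounds, model = model, note = note, n = n),
    class = "txtl_fit"
  )
}

#' @export
print.txtl_fit <- function(x, ...) {
  cat("<txtl_fit> ", x$model, "\n", sep = "")
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-12s %.6g\n", nm, x$estimates[[nm]]))
  }
  cat(sprintf("  rss = %.4g, converged = %s, n = %d\n",
              x$rss, x$converged, x$n))
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a model fit
#'
#' @param x A `txtl_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate` (plus `lower`/`upper`
#'   bounds when the fit was bounded).
#' @export
tidy.txtl_fit <- function(x, ...) {
  out <- tibble::tibble(term = names(x$estimates),
                        estimate = unname(unlist(x$estimates)))
  if (!is.null(x$bounds)) {
    out$lower <- x$bounds$lower[out$term]
    out$upper <- x$bounds$upper[out$term]
  }
  out
}

#' One-row fit summary
#'
#' @param x A `txtl_fit` object.
#' @param ... Unused.
#' @return A tibble with `rss`, `converged`, `n`, `note`.
#' @export
glance.txtl_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged, n = x$n,
                 note = x$note %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a first-order exponential decay
#'
#' Fits `A * exp(-k * t)` to a decay trace, e.g. an mRNA degradation assay,
#' returning the rate constant and the mean lifetime `1/k`. When every
#' signal value is positive the fit runs as ordinary least squares on
#' `log(signal)` (exact for multiplicative noise); otherwise it falls back
#' to direct nonlinear least squares.
#'
#' @param trace Data frame with columns `time_s` and `signal_nM`.
#' @return A `txtl_fit` with estimates `k` (1/s), `A` (nM) and
#'   `mean_lifetime_s`.
#' @examples
#' tr <- tibble::tibble(time_s = seq(0, 7200, 180),
#'                      signal_nM = 100 * exp(-8.25e-4 * seq(0, 7200, 180)))
#' tidy(fit_exponential_decay(tr))
#' @export
fit_exponential_decay <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "signal_nM") %in% names(trace)))
  t <- trace$time_s
  y <- trace$signal_nM
  if (length(t) < 3) stop("need at least 3 points", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) {
    stop("time_s must be strictly increasing", call. = FALSE)
  }
  if (all(y <= 0)) stop("signal is non-positive everywhere", call. = FALSE)
  if (all(y > 0)) {
    fit <- stats::lm(log(y) ~ t)
    k <- -unname(stats::coef(fit)[2])
    A <- exp(unname(stats::coef(fit)[1]))
    pred <- A * exp(-k * t)
    rss <- sum((y - pred)^2)
    conv <- TRUE
  } else {
    keep <- y > 0
    k0 <- max(1e-6, -stats::coef(stats::lm(log(y[keep]) ~ t[keep]))[2])
    fit <- minpack.lm::nlsLM(
      y ~ A * exp(-k * t),
      start = list(A = max(y), k = k0),
      lower = c(A = 0, k = 0),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    )
    cf <- stats::coef(fit)
    k <- unname(cf["k"]); A <- unname(cf["A"])
    rss <- sum(stats::resid(fit)^2)
    conv <- fit$convInfo$isConv
  }
  new_txtl_fit(list(k = k, A = A, mean_lifetime_s = 1 / k),
               rss = rss, converged = conv,
               model = "A * exp(-k t)", n = length(t))
}

#' Fit a first-order maturation (saturating rise)
#'
#' Fits `F_inf * (1 - exp(-k_mat * t))` to a fluorescence rise measured
#' after arresting translation, giving the reporter maturation rate. The
#' fitted rate is invariant to rescaling of the signal amplitude.
#'
#' @param trace Data frame with columns `time_s` and `signal_nM`.
#' @return A `txtl_fit` with estimates `k_mat` (1/s) and `F_inf` (nM).
#' @export
fit_maturation <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "signal_nM") %in% names(trace)))
  t <- trace$time_s
  y <- trace$signal_nM
  if (length(t) < 3) stop("need at least 3 points", call. = FALSE)
  if (all(y <= 0)) stop("signal is non-positive everywhere", call. = FALSE)
  Fmax <- max(y)
  # crude rate guess from the time to reach half the plateau
  t_half <- t[which(y >= Fmax / 2)[1]]
  k0 <- if (is.na(t_half) || t_half <= 0) 1 / max(t) else log(2) / t_half
  fit <- minpack.lm::nlsLM(
    y ~ F_inf * (1 - exp(-k_mat * t)),
    start = list(F_inf = Fmax, k_mat = k0),
    lower = c(F_inf = 0, k_mat = 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  cf <- stats::coef(fit)
  new_txtl_fit(list(k_mat = unname(cf["k_mat"]), F_inf = unname(cf["F_inf"])),
               rss = sum(stats::resid(fit)^2),
               converged = fit$convInfo$isConv,
               model = "F_inf * (1 - exp(-k_mat t))", n = length(t))
}

#' Transcription initiation frequency from a measured mRNA steady state
#'
#' Inverts the steady-state relation `m_ss = k_TX / kdeg_m * P70`:
#' `k_TX = m_ss / (plasmid * mean_lifetime)`.
#'
#' @param m_ss Steady-state mRNA, nM.
#' @param plasmid Plasmid concentration, nM (> 0).
#' @param mean_lifetime Mean mRNA lifetime `1/kdeg_m`, s.
#' @return `k_TX`, 1/s.
#' @examples
#' ktx_from_mrna_steady_state(25, 1, 27 * 60)  # ~1.5e-2 /s
#' @export
ktx_from_mrna_steady_state <- function(m_ss, plasmid, mean_lifetime) {
  if (plasmid <= 0) stop("plasmid must be > 0", call. = FALSE)
  if (mean_lifetime <= 0) stop("mean_lifetime must be > 0", call. = FALSE)
  if (m_ss < 0) stop("m_ss must be >= 0", call. = FALSE)
  m_ss / (plasmid * mean_lifetime)
}

#' Product of catalytic rate constants from a measured linear-regime rate
#'
#' Inverts the linear-regime accumulation law
#' `rate = kcat_p * kcat_m / kdeg_m * P70`:
#' `kcat_p * kcat_m = rate * kdeg_m / plasmid`.
#'
#' @param max_rate Maximum protein synthesis rate, nM/s.
#' @param plasmid Plasmid concentration, nM (> 0).
#' @param kdeg_m First-order mRNA degradation rate, 1/s.
#' @return The product `kcat_p * kcat_m`, 1/s^2.
#' @examples
#' kcat_product_from_rate(0.5, 1, 8.25e-4)  # ~4e-4 /s^2
#' @export
kcat_product_from_rate <- function(max_rate, plasmid, kdeg_m) {
  if (plasmid <= 0) stop("plasmid must be > 0", call. = FALSE)
  if (max_rate < 0 || kdeg_m <= 0) {
    stop("max_rate must be >= 0 and kdeg_m > 0", call. = FALSE)
  }
  max_rate * kdeg_m / plasmid
}

#' Fit catalytic rate constants to a rate-versus-plasmid curve
#'
#' Bounded least squares for `(kcat_m, kcat_p)` against measured maximum
#' synthesis rates over a plasmid concentration grid, holding every other
#' constant (in particular the weakly identifiable Michaelis constants)
#' fixed at its value in `base_params`. The model rate at each concentration
#' is the analytic regime-II steady-state rate ([steady_state_rate()]).
#' Optimisation runs in log-parameter space with bounds `(0, 0.5]` 1/s,
#' from three starts spread one decade around the initial guess (seeded
#' jitter). When the measured curve never leaves the linear regime only the
#' product `kcat_m * kcat_p` is constrained; the fit then carries an
#' identifiability note.
#'
#' @param data Data frame with columns `plasmid_nM` and
#'   `max_rate_nM_per_s` (>= 4 concentrations).
#' @param base_params A [txtl_params()] object supplying all fixed constants.
#' @param seed Seed for the multi-start jitter.
#' @return A `txtl_fit` with estimates `kcat_m`, `kcat_p` and
#'   `kcat_product`; inspect with [tidy()] / [glance()].
#' @export
fit_kcats_to_rate_curve <- function(data, base_params, seed = 1L) {
  stopifnot(is.data.frame(data),
            all(c("plasmid_nM", "max_rate_nM_per_s") %in% names(data)),
            inherits(base_params, "txtl_params"))
  concs <- data$plasmid_nM
  rates <- data$max_rate_nM_per_s
  if (length(concs) < 4) stop("need >= 4 concentrations", call. = FALSE)
  if (all(rates == 0)) stop("all measured rates are zero", call. = FALSE)

  model_rates <- function(kcat_m, kcat_p) {
    p <- set_params(base_params, kcat_m = kcat_m, kcat_p = kcat_p)
    vapply(concs, function(cc) {
      if (cc == 0) return(0)
      suppressWarnings(steady_state_rate(set_params(p, P70 = cc)))
    }, numeric(1))
  }
  obj <- function(lp) {
    r <- model_rates(10^lp[1], 10^lp[2])
    sum((r - rates)^2)
  }

  # initial guess: product from the lowest-concentration point, split in the
  # same ratio as the base parameter set
  i0 <- which(concs > 0)[1]
  prod0 <- max(rates[i0] * kdeg_m(base_params) / concs[i0], 1e-10)
  ratio <- base_params$kcat_m / base_params$kcat_p
  g_m <- min(sqrt(prod0 * ratio), 0.5)
  g_p <- min(sqrt(prod0 / ratio), 0.5)

  lower <- log10(c(1e-6, 1e-6))
  upper <- log10(c(0.5, 0.5))
  set.seed(seed)
  starts <- list(log10(c(g_m, g_p)))
  for (i in 1:2) {
    starts[[i + 1]] <- pmin(pmax(
      log10(c(g_m, g_p)) + stats::runif(2, -0.5, 0.5), lower), upper)
  }
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, obj, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = 300))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  kcat_m <- 10^best$par[1]
  kcat_p <- 10^best$par[2]

  # identifiability: a curve that never departs from proportionality only
  # constrains the product kcat_m * kcat_p
  pos <- concs > 0
  rp <- rates[pos] / concs[pos]
  never_saturates <- (max(rp) - min(rp)) <= 0.1 * max(rp)
  note <- if (never_saturates) {
    "curve never saturates: only the product kcat_m*kcat_p is identifiable"
  } else {
    NULL
  }
  new_txtl_fit(
    list(kcat_m = kcat_m, kcat_p = kcat_p,
         kcat_product = kcat_m * kcat_p),
    rss = best$value, converged = best$convergence == 0,
    bounds = list(lower = c(kcat_m = 1e-6, kcat_p = 1e-6,
                            kcat_product = 1e-12),
                  upper = c(kcat_m = 0.5, kcat_p = 0.5,
                            kcat_product = 0.25)),
    model = "steady-state rate curve", note = note, n = length(concs)
  )
}

#' Promoter/UTR strength table from rate curves
#'
#' Computes, for each construct, the rate of reporter synthesis per nM of
#' plasmid in the linear regime (a through-origin regression over the
#' linear-regime points), reported in nM/h per nM plasmid, and the strength
#' relative to a reference construct (by convention the strongest pair,
#' P70a-UTR1).
#'
#' @param data Long data frame with columns `plasmid_nM`,
#'   `max_rate_nM_per_s`, `promoter`, `utr` covering one or more constructs.
#' @param reference Length-2 character vector `c(promoter, utr)` naming the
#'   construct whose strength defines 1; defaults to `"P70a"`, `"UTR1"`,
#'   falling back to the strongest construct present.
#' @param linear_tol Relative departure from proportionality beyond which a
#'   point is excluded from the linear regime.
#' @return A tibble with one row per construct: `promoter`, `utr`,
#'   `rate_per_plasmid_nM_h` and `relative_strength`.
#' @export
part_strength_table <- function(data, reference = c("P70a", "UTR1"),
                                linear_tol = 0.1) {
  stopifnot(is.data.frame(data),
            all(c("plasmid_nM", "max_rate_nM_per_s", "promoter", "utr")
                %in% names(data)))
  slope_one <- function(d) {
    d <- d[d$plasmid_nM > 0, , drop = FALSE]
    if (nrow(d) < 2) stop("construct needs >= 2 positive-plasmid points",
                          call. = FALSE)
    rp <- d$max_rate_nM_per_s / d$plasmid_nM
    # linear regime: rate-per-plasmid within tolerance of its value at the
    # lowest concentrations (take the max ratio as the linear reference,
    # since saturation only pulls the ratio down)
    ref <- max(rp)
    lin <- rp >= (1 - linear_tol) * ref
    if (!any(lin)) stop("no linear-regime points for construct", call. = FALSE)
    sum(d$max_rate_nM_per_s[lin] * d$plasmid_nM[lin]) /
      sum(d$plasmid_nM[lin]^2)
  }
  out <- data |>
    dplyr::group_by(.data$promoter, .data$utr) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(rate_per_plasmid_nM_h = slope_one(d) * 3600)
    }) |>
    dplyr::ungroup()
  ref_row <- out$promoter == reference[1] & out$utr == reference[2]
  ref_val <- if (any(ref_row)) {
    out$rate_per_plasmid_nM_h[ref_row][1]
  } else {
    max(out$rate_per_plasmid_nM_h)
  }
  out$relative_strength <- out$rate_per_plasmid_nM_h / ref_val
  dplyr::arrange(out, dplyr::desc(.data$relative_strength))
}
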