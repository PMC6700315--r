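#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a kinetics trace
#'
#' Shows mRNA, dark and mature reporter against time in hours, with the
#' transient and steady-state regimes visible as curvature and linear
#' accumulation.
#'
#' @param object A `txtl_trace` from [simulate_kinetics()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.txtl_trace <- function(object, ...) {
  d <- tibble::as_tibble(object)[, c("time_s", "mrna_nM", "degfp_dark_nM",
                                     "degfp_mat_nM")] |>
    tidyr::pivot_longer(-"time_s", names_to = "species",
                        values_to = "conc_nM") |>
    dplyr::mutate(species = factor(.data$species,
                                   levels = c("mrna_nM", "degfp_dark_nM",
                                              "degfp_mat_nM"),
                                   labels = c("mRNA", "deGFP (dark)",
                                              "deGFP (mature)")))
  ggplot2::ggplot(d, ggplot2::aes(.data$time_s / 3600, .data$conc_nM,
                                  colour = .data$species)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "time (h)", y = "concentration (nM)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a rate-versus-plasmid curve
#'
#' Points coloured by regime (linear vs ribosome-saturated), with the
#' through-origin linear-regime slope drawn as a reference line.
#'
#' @param object A `txtl_rate_curve` from [rate_vs_plasmid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.txtl_rate_curve <- function(object, ...) {
  slope <- attr(object, "slope_linear")
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$plasmid_nM,
                                    .data$max_rate_nM_per_s)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$regime), size = 2) +
    ggplot2::labs(x = "plasmid (nM)", y = "max synthesis rate (nM/s)",
                  colour = "regime") +
    ggplot2::theme_minimal()
  if (is.finite(slope %||% NA_real_)) {
    p <- p + ggplot2::geom_abline(slope = slope, intercept = 0,
                                  linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a sensitivity scan
#'
#' One rate curve per scan factor, on a log colour ordering.
#'
#' @param object A `txtl_sensitivity` from [sensitivity_scan()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.txtl_sensitivity <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$factor <- factor(d$factor, levels = sort(unique(d$factor)))
  ggplot2::ggplot(d, ggplot2::aes(.data$plasmid_nM,
                                  .data$max_rate_nM_per_s,
                                  colour = .data$factor,
                                  group = .data$factor)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(title = unique(d$parameter), x = "plasmid (nM)",
                  y = "max synthesis rate (nM/s)", colour = "factor") +
    ggplot2::theme_minimal()
}

#' Plot resource depletion profiles
#'
#' Free core RNA polymerase and free ribosomes against plasmid
#' concentration; the sharp ribosome drop marks the linear-to-saturated
#' transition.
#'
#' @param object A `txtl_depletion` from [resource_depletion_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.txtl_depletion <- function(object, ...) {
  d <- tibble::as_tibble(object)[, c("plasmid_nM", "E0_nM", "R0_nM")] |>
    tidyr::pivot_longer(-"plasmid_nM", names_to = "pool",
                        values_to = "conc_nM") |>
    dplyr::mutate(pool = dplyr::recode(.data$pool,
                                       E0_nM = "free core RNAP",
                                       R0_nM = "free ribosomes"))
  ggplot2::ggplot(d, ggplot2::aes(.data$plasmid_nM, .data$conc_nM,
                                  colour = .data$pool)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "plasmid (nM)", y = "free pool (nM)", colour = NULL) +
    ggplot2::theme_minimal()
}
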