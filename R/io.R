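#' Convert a mass concentration to molarity
#'
#' `conc * 1000 / molar_mass` converts mg/mL to µM given a molar mass in
#' kDa; for the 25.4 kDa deGFP reporter, 1 mg/mL is 39.37 µM, the constant
#' used to calibrate plate-reader fluorescence against a pure standard.
#'
#' @param conc Mass concentration, mg/mL.
#' @param molar_mass Molar mass, kDa.
#' @return Molar concentration, µM.
#' @examples
#' mgml_to_micromolar(1, 25.4)
#' @export
mgml_to_micromolar <- function(conc, molar_mass) {
  if (any(molar_mass <= 0)) stop("molar_mass must be > 0", call. = FALSE)
  if (any(conc < 0)) stop("conc must be >= 0", call. = FALSE)
  conc * 1000 / molar_mass
}

#' Read a parameter configuration from JSON
#'
#' The config is a flat JSON object keyed by [txtl_params()] field names
#' (units nM and s, as documented in the bundled schema
#' `system.file("extdata", "params-schema.json", package = "txtlsim")`).
#' Unknown keys are rejected; omitted keys take the package defaults.
#'
#' @param path Path to a JSON file.
#' @return A [txtl_params()] object.
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!names(raw) %in% c("comment", "description")]
  unknown <- setdiff(names(raw), txtl_param_names())
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(txtl_params, raw)
}

#' Write a parameter set to JSON
#'
#' @param params A [txtl_params()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "txtl_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

# JSON sidecar recording provenance for any written artifact
write_manifest <- function(path, params = NULL, extra = list()) {
  manifest <- c(
    list(package = "txtlsim",
         version = as.character(utils::packageVersion("txtlsim")),
         created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    if (!is.null(params)) list(parameters = unclass(params)),
    extra
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a kinetics trace to CSV
#'
#' Writes `time_s,mrna_nM,degfp_dark_nM,degfp_mat_nM,E0_nM,R0_nM` (RFC
#' 4180, header row) plus a `.manifest.json` sidecar embedding the package
#' version and the exact parameter set used.
#'
#' @param trace A trace from [simulate_kinetics()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  cols <- c("time_s", "mrna_nM", "degfp_dark_nM", "degfp_mat_nM")
  alloc <- intersect(c("E0_nM", "R0_nM"), names(trace))
  readr::write_csv(trace[, c(cols, alloc)], path)
  write_manifest(path, params = attr(trace, "params"))
  invisible(path)
}

#' Read a kinetics trace CSV
#' @param path CSV path written by [write_trace_csv()].
#' @return A tibble.
#' @export
read_trace_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read rate-curve data CSV
#'
#' Columns `plasmid_nM,max_rate_nM_per_s,promoter,utr`.
#'
#' @param data Rate-curve data frame.
#' @param path CSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_rate_curve_csv <- function(data, path) {
  stopifnot(all(c("plasmid_nM", "max_rate_nM_per_s") %in% names(data)))
  d <- tibble::as_tibble(data)
  if (!"promoter" %in% names(d)) d$promoter <- NA_character_
  if (!"utr" %in% names(d)) d$utr <- NA_character_
  readr::write_csv(d[, c("plasmid_nM", "max_rate_nM_per_s",
                         "promoter", "utr")], path)
  write_manifest(path, params = attr(data, "params"))
  invisible(path)
}

#' @rdname write_rate_curve_csv
#' @export
read_rate_curve_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read a plate-reader run CSV
#'
#' Columns `time_s,well,condition,value_nM`.
#'
#' @param run A plate-run tibble (e.g. from [generate_kinetics()]).
#' @param path CSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_plate_run_csv <- function(run, path) {
  stopifnot(all(c("time_s", "well", "condition", "value_nM") %in% names(run)))
  readr::write_csv(
    tibble::as_tibble(run)[, c("time_s", "well", "condition", "value_nM")],
    path)
  noise <- attr(run, "noise")
  write_manifest(path, params = attr(run, "params"),
                 extra = if (!is.null(noise)) list(noise = unclass(noise))
                         else list())
  invisible(path)
}

#' @rdname write_plate_run_csv
#' @export
read_plate_run_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write / read a decay trace CSV
#'
#' Columns `time_s,signal_nM`.
#'
#' @param trace A decay-trace data frame.
#' @param path CSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_decay_csv <- function(trace, path) {
  stopifnot(all(c("time_s", "signal_nM") %in% names(trace)))
  readr::write_csv(tibble::as_tibble(trace)[, c("time_s", "signal_nM")], path)
  gt <- attr(trace, "ground_truth")
  write_manifest(path,
                 extra = if (!is.null(gt)) list(ground_truth = as.list(gt))
                         else list())
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Serialize a fit result to JSON
#'
#' @param fit A `txtl_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "txtl_fit"))
  jsonlite::write_json(
    list(package = "txtlsim",
         version = as.character(utils::packageVersion("txtlsim")),
         model = fit$model,
         estimates = fit$estimates,
         rss = fit$rss, converged = fit$converged,
         bounds = fit$bounds, note = fit$note, n = fit$n),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
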