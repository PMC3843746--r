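MEASUREMENT_SCHEMA <- "fretcal-measurements-v1"

#' Write and read cluster measurement tables
#'
#' Plain CSV with a schema-version comment line on top; the reader rejects
#' files carrying an unknown schema tag so silent format drift fails
#' loudly.
#'
#' @param measurements tibble from [quantify_cells()] (or compatible).
#' @param path file path.
#' @return `read_measurements()` returns a tibble;
#'   `write_measurements()` its input, invisibly.
#' @export
write_measurements <- function(measurements, path) {
  stopifnot(is.data.frame(measurements))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", MEASUREMENT_SCHEMA), con)
  utils::write.csv(measurements, con, row.names = FALSE)
  invisible(measurements)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  first <- readLines(path, n = 1)
  if (!identical(first, paste0("# ", MEASUREMENT_SCHEMA))) {
    abort(sprintf(
      "Unrecognized measurement schema in %s (found %s, expected '# %s').",
      path, dQuote(first), MEASUREMENT_SCHEMA), class = "fretcal_format_error")
  }
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Write and read three-channel stacks as multi-page TIFF plus sidecar
#'
#' Pages are channel-major (all donor planes, then acceptor, then FRET, in
#' the sidecar's `channel_order`); the JSON sidecar declares
#' `channel_order`, `pixel_size_nm`, `z_step_nm` and the intensity `scale`
#' used to map counts into the 16-bit TIFF range. Integer-valued voxels
#' below the scale round-trip exactly.
#'
#' @param stacks named list of three [channel_stack()]s.
#' @param path TIFF path; the sidecar is written at `<path>.json` unless
#'   `sidecar` is given.
#' @param sidecar sidecar JSON path.
#' @return `read_stack()` returns a named list of [channel_stack()]s.
#' @export
write_stack <- function(stacks, path, sidecar = paste0(path, ".json")) {
  chans <- names(stacks)
  stopifnot(length(chans) >= 1, all(vapply(stacks, inherits, logical(1),
    "channel_stack")))
  peak <- max(vapply(stacks, function(s) max(s$voxels), numeric(1)))
  # 16-bit samples: integer counts up to 65535 round-trip exactly
  scale <- if (peak <= 65535) 65535 else peak
  pages <- list()
  for (ch in chans) {
    v <- stacks[[ch]]$voxels
    for (z in seq_len(dim(v)[3])) {
      pages[[length(pages) + 1]] <- v[, , z] / scale
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(
    channel_order = chans,
    pixel_size_nm = stacks[[1]]$pixel_size_nm,
    z_step_nm = stacks[[1]]$z_step_nm,
    scale = scale
  )
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(sidecar)) {
    abort(sprintf("Missing sidecar %s.", sidecar), class = "fretcal_config_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (key in c("channel_order", "pixel_size_nm", "z_step_nm")) {
    if (is.null(meta[[key]])) {
      abort(sprintf("Sidecar %s lacks required key '%s'.", sidecar, key),
        class = "fretcal_config_error")
    }
  }
  scale <- meta$scale %||% 1
  pages <- tiff::readTIFF(path, all = TRUE)
  n_chan <- length(meta$channel_order)
  if (length(pages) %% n_chan != 0) {
    abort(sprintf("%d TIFF pages not divisible by %d channels.",
      length(pages), n_chan), class = "fretcal_format_error")
  }
  nz <- length(pages) %/% n_chan
  out <- list()
  for (c_i in seq_len(n_chan)) {
    planes <- pages[(c_i - 1) * nz + seq_len(nz)]
    vox <- array(0, dim = c(dim(planes[[1]]), nz))
    for (z in seq_len(nz)) vox[, , z] <- round(planes[[z]] * scale, 6)
    out[[meta$channel_order[c_i]]] <- channel_stack(
      vox, pixel_size_nm = meta$pixel_size_nm, z_step_nm = meta$z_step_nm,
      channel = meta$channel_order[c_i])
  }
  out
}

#' Save and load analysis parameter profiles as JSON
#'
#' Round-trips the three parameter objects (spectral coefficients,
#' calibration line, Förster parameters) so an analysis is reproducible
#' from its config file. Unknown top-level keys are rejected.
#'
#' @param config list with any of `coefficients`
#'   ([spectral_coefficients()]), `calibration` (`fret_calibration`),
#'   `forster` ([forster_params()]).
#' @param path JSON path.
#' @return `read_fret_config()` returns the reconstructed list.
#' @export
write_fret_config <- function(config, path) {
  known <- c("coefficients", "calibration", "forster")
  extra <- setdiff(names(config), known)
  if (length(extra) > 0) {
    abort(paste0("Unknown config entries: ", paste(extra, collapse = ", ")),
      class = "fretcal_config_error")
  }
  payload <- list(schema = "fretcal-config-v1")
  if (!is.null(config$coefficients)) {
    payload$coefficients <- unclass(config$coefficients)
  }
  if (!is.null(config$calibration)) {
    cal <- config$calibration
    payload$calibration <- list(
      slope = cal$slope, intercept = cal$intercept, r_squared = cal$r_squared,
      ci95_slope = cal$ci95_slope, ci95_intercept = cal$ci95_intercept,
      n_points = cal$n_points)
  }
  if (!is.null(config$forster)) payload$forster <- unclass(config$forster)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_fret_config
#' @export
read_fret_config <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "fretcal-config-v1")) {
    abort(sprintf("Unknown config schema in %s.", path),
      class = "fretcal_config_error")
  }
  known <- c("schema", "coefficients", "calibration", "forster")
  extra <- setdiff(names(p), known)
  if (length(extra) > 0) {
    abort(paste0("Unknown config entries: ", paste(extra, collapse = ", ")),
      class = "fretcal_config_error")
  }
  out <- list()
  if (!is.null(p$coefficients)) {
    co <- p$coefficients
    out$coefficients <- spectral_coefficients(
      co$alpha, co$beta, co$alpha_sem %||% 0, co$beta_sem %||% 0,
      co$n_donor %||% NA_integer_, co$n_acceptor %||% NA_integer_)
  }
  if (!is.null(p$calibration)) {
    ca <- p$calibration
    out$calibration <- calibration_model(
      ca$slope, ca$intercept, ca$r_squared %||% NA_real_,
      unlist(ca$ci95_slope) %||% c(NA_real_, NA_real_),
      unlist(ca$ci95_intercept) %||% c(NA_real_, NA_real_),
      ca$n_points %||% NA_integer_)
  }
  if (!is.null(p$forster)) {
    fo <- p$forster
    out$forster <- forster_params(fo$r0_nm, fo$maturation_fraction,
                                  fo$kappa_squared %||% 0.66)
  }
  out
}
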