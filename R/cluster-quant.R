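#' Locate the in-focus plane of a fluorescent cluster
#'
#' Searches for the brightest voxel in a cylindrical neighborhood of a seed
#' position: all planes are searched, but only pixels within
#' `search_radius_px` of `(seed_x, seed_y)` laterally. This mirrors the
#' click-then-search workflow used for kinetochore clusters: the user (or a
#' clicks table) supplies a rough position and the brightest nearby voxel
#' defines the focal plane and lateral peak.
#'
#' Ties are broken deterministically toward the lowest plane index, then the
#' lowest row (y), then the lowest column (x).
#'
#' @param stack a [channel_stack()].
#' @param seed_x,seed_y 1-based pixel coordinates of the seed.
#' @param search_radius_px lateral search radius in pixels (>= 1).
#' @return A list with elements `z`, `x`, `y`, `value` and `no_signal`
#'   (`TRUE` when every voxel in the neighborhood is zero, in which case the
#'   seed position and plane 1 are returned).
#' @export
find_focus_plane <- function(stack, seed_x, seed_y, search_radius_px = 4) {
  stopifnot(inherits(stack, "channel_stack"), search_radius_px >= 1)
  d <- dim(stack$voxels)
  seed_x <- as.integer(round(seed_x)); seed_y <- as.integer(round(seed_y))
  if (seed_x < 1L || seed_x > d[2] || seed_y < 1L || seed_y > d[1]) {
    abort(sprintf("Seed (%d, %d) outside %d x %d image.", seed_x, seed_y, d[2], d[1]),
      class = "fretcal_input_error")
  }
  r <- search_radius_px
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= r^2, , drop = FALSE]
  xs <- seed_x + off$dx; ys <- seed_y + off$dy
  keep <- xs >= 1L & xs <= d[2] & ys >= 1L & ys <= d[1]
  xs <- xs[keep]; ys <- ys[keep]
  nz <- d[3]
  idx <- cbind(
    y = rep(ys, nz),
    x = rep(xs, nz),
    z = rep(seq_len(nz), each = length(xs))
  )
  vals <- stack$voxels[idx]
  if (all(vals == 0)) {
    return(list(z = 1L, x = seed_x, y = seed_y, value = 0, no_signal = TRUE))
  }
  best <- which(vals == max(vals))
  # deterministic tie-break: lowest z, then y, then x
  ord <- order(idx[best, "z"], idx[best, "y"], idx[best, "x"])
  b <- best[ord[1]]
  list(z = as.integer(idx[b, "z"]), x = as.integer(idx[b, "x"]),
       y = as.integer(idx[b, "y"]), value = vals[b], no_signal = FALSE)
}

# corrected intensity for a 6x6 box with top-left pixel (x0, y0):
# sum of the 6x6 minus 36 * median of the 28-pixel rim of the concentric 8x8
meta_box_corrected <- function(plane, x0, y0) {
  box <- plane[y0:(y0 + 5L), x0:(x0 + 5L)]
  ring <- plane[(y0 - 1L):(y0 + 6L), (x0 - 1L):(x0 + 6L)]
  rim <- ring[-(2:7), ] # top and bottom rows (16 px)
  rim <- c(rim, ring[2:7, c(1L, 8L)]) # left/right edges (12 px)
  sum(box) - 36 * median(rim)
}

#' Box photometry for closely spaced (metaphase) clusters
#'
#' Places a 6 x 6 pixel signal box near the detected peak, choosing among
#' placements within +/- 2 pixels the one that maximizes the cumulative
#' intensity of its central 4 x 4 region. Background is the per-pixel median
#' of the 28-pixel rim of the concentric 8 x 8 box, scaled by the 36 signal
#' pixels; the median (rather than the mean) keeps a neighboring cluster
#' that intrudes into the rim from biasing the background. The corrected
#' intensity may be negative and is reported as-is.
#'
#' @param plane numeric matrix, one image plane (`[y, x]`).
#' @param peak_x,peak_y 1-based pixel coordinates of the intensity peak.
#' @return A list with `intensity` (background-corrected integrated counts)
#'   and `roi` (placement record shared across channels downstream).
#' @export
measure_metaphase_cluster <- function(plane, peak_x, peak_y) {
  stopifnot(is.matrix(plane))
  peak_x <- as.integer(round(peak_x)); peak_y <- as.integer(round(peak_y))
  base_x <- peak_x - 2L; base_y <- peak_y - 2L
  cand <- expand.grid(dx = -2:2, dy = -2:2)
  x0 <- base_x + cand$dx; y0 <- base_y + cand$dy
  # the concentric 8x8 (origin - 1 .. origin + 6) must fit inside the image
  ok <- x0 >= 2L & y0 >= 2L & (x0 + 6L) <= ncol(plane) & (y0 + 6L) <= nrow(plane)
  if (!any(ok)) {
    abort(sprintf(
      "8 x 8 background box around peak (%d, %d) does not fit inside the image.",
      peak_x, peak_y), class = "fretcal_boundary_error")
  }
  x0 <- x0[ok]; y0 <- y0[ok]
  central <- vapply(seq_along(x0), function(i) {
    sum(plane[(y0[i] + 1L):(y0[i] + 4L), (x0[i] + 1L):(x0[i] + 4L)])
  }, numeric(1))
  best <- which(central == max(central))
  ord <- order(y0[best], x0[best])
  i <- best[ord[1]]
  roi <- list(
    method = "metaphase_box",
    box_origin = c(x = x0[i], y = y0[i]),
    peak = c(x = peak_x, y = peak_y),
    mask_pixel_count = 36L
  )
  list(intensity = meta_box_corrected(plane, x0[i], y0[i]), roi = roi)
}

gauss2d <- function(x, y, A, x0, y0, sx, sy, b) {
  b + A * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2)))
}

#' Gaussian-mask photometry for isolated (anaphase) clusters
#'
#' Fits a 2-D Gaussian plus constant offset to the pixels in a square window
#' around the peak, then integrates the offset-subtracted pixel values inside
#' the elliptical contour at `mask_sigma` standard deviations (default 2.5,
#' which captures ~95.6% of the spot mass for a circular Gaussian).
#'
#' @param plane numeric matrix (`[y, x]`).
#' @param peak_x,peak_y 1-based peak position.
#' @param fit_window_px odd width of the square fit window (>= 5).
#' @param mask_sigma elliptical mask radius in fitted sigma units.
#' @return A list with `intensity`, `roi` (fit parameters, mask definition)
#'   and `fit` (the `nls` object).
#' @export
measure_anaphase_cluster <- function(plane, peak_x, peak_y,
                                     fit_window_px = 15, mask_sigma = 2.5) {
  stopifnot(is.matrix(plane), fit_window_px >= 5)
  peak_x <- as.integer(round(peak_x)); peak_y <- as.integer(round(peak_y))
  half <- fit_window_px %/% 2L
  xs <- (peak_x - half):(peak_x + half)
  ys <- (peak_y - half):(peak_y + half)
  if (min(xs) < 1L || min(ys) < 1L || max(xs) > ncol(plane) || max(ys) > nrow(plane)) {
    abort(sprintf("Fit window around (%d, %d) clips the image edge.", peak_x, peak_y),
      class = "fretcal_boundary_error")
  }
  g <- expand.grid(x = xs, y = ys)
  g$v <- plane[cbind(g$y, g$x)]
  b0 <- median(g$v)
  a0 <- max(g$v) - b0
  if (a0 <= 0 || sd(g$v) == 0) {
    abort("Gaussian fit failed: no spot above background in the fit window.",
      class = "fretcal_fit_failed")
  }
  top <- g[which.max(g$v), ]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ gauss2d(x, y, A, x0, y0, sx, sy, b),
      data = g,
      start = list(A = a0, x0 = top$x, y0 = top$y, sx = 1.5, sy = 1.5, b = b0),
      lower = c(A = 0, x0 = min(xs), y0 = min(ys), sx = 0.3, sy = 0.3, b = -Inf),
      upper = c(A = Inf, x0 = max(xs), y0 = max(ys), sx = fit_window_px,
                sy = fit_window_px, b = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    abort("Gaussian fit failed: optimizer did not converge.",
      class = "fretcal_fit_failed")
  }
  p <- as.list(coef(fit))
  if (p$A <= 0) {
    abort(sprintf("Gaussian fit failed: non-positive amplitude (residual sd %.3g).",
      sd(residuals(fit))), class = "fretcal_fit_failed")
  }
  mask <- ((g$x - p$x0) / p$sx)^2 + ((g$y - p$y0) / p$sy)^2 <= mask_sigma^2
  roi <- list(
    method = "anaphase_gaussian",
    center = c(x = p$x0, y = p$y0),
    sigma = c(x = p$sx, y = p$sy),
    amplitude = p$A,
    offset = p$b,
    mask_sigma = mask_sigma,
    fit_window_px = as.integer(fit_window_px),
    peak = c(x = peak_x, y = peak_y),
    mask_pixel_count = sum(mask)
  )
  list(intensity = sum(g$v[mask] - p$b), roi = roi, fit = fit)
}

# amplitude + offset of `plane` against a fixed Gaussian shape, by linear LS;
# returns the mask-integrated, offset-subtracted intensity
anaphase_apply_roi <- function(plane, roi) {
  half <- roi$fit_window_px %/% 2L
  xs <- (roi$peak[["x"]] - half):(roi$peak[["x"]] + half)
  ys <- (roi$peak[["y"]] - half):(roi$peak[["y"]] + half)
  g <- expand.grid(x = xs, y = ys)
  g$v <- plane[cbind(g$y, g$x)]
  shape <- exp(-((g$x - roi$center[["x"]])^2 / (2 * roi$sigma[["x"]]^2) +
                 (g$y - roi$center[["y"]])^2 / (2 * roi$sigma[["y"]]^2)))
  co <- coef(lm(g$v ~ shape))
  mask <- ((g$x - roi$center[["x"]]) / roi$sigma[["x"]])^2 +
    ((g$y - roi$center[["y"]]) / roi$sigma[["y"]])^2 <= roi$mask_sigma^2
  sum(g$v[mask] - co[[1]])
}

#' Quantify one cluster across the donor, acceptor and FRET channels
#'
#' The focal plane and region of interest are determined once, on the
#' reference channel (default: donor, the brightest and most uniform
#' channel), and then applied unchanged to all three channels at the same
#' plane, so that every channel is integrated over the identical set of
#' pixels. For the Gaussian (anaphase) method the spot shape fitted on the
#' reference channel is reused and only a per-channel amplitude and constant
#' background are refitted linearly.
#'
#' @param stacks named list with elements `donor`, `acceptor`, `fret`, each
#'   a [channel_stack()] of identical dimensions.
#' @param seed_x,seed_y click position near the cluster.
#' @param phase `"metaphase"` (box photometry) or `"anaphase"` (Gaussian
#'   mask photometry).
#' @param cell_id identifier copied into the output row.
#' @param reference_channel channel used to find focus and define the ROI.
#' @param search_radius_px lateral focus-search radius.
#' @param fit_window_px,mask_sigma passed to [measure_anaphase_cluster()].
#' @return A one-row tibble: `cell_id`, `phase`, `I_donor`, `I_acceptor`,
#'   `I_fret`, `focus_z`, `roi_method`, `roi_params` (JSON), `fit_ok`.
#'   A failed Gaussian fit (e.g. a flat field) yields zero intensities with
#'   `fit_ok = FALSE` rather than an error.
#' @export
quantify_cell <- function(stacks, seed_x, seed_y,
                          phase = c("metaphase", "anaphase"),
                          cell_id = "cell", reference_channel = "donor",
                          search_radius_px = 4, fit_window_px = 15,
                          mask_sigma = 2.5) {
  phase <- match.arg(phase)
  chans <- c("donor", "acceptor", "fret")
  if (!all(chans %in% names(stacks))) {
    abort("`stacks` must contain donor, acceptor and fret channels.",
      class = "fretcal_input_error")
  }
  dims <- lapply(stacks[chans], function(s) dim(s$voxels))
  if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("All channel stacks must have identical dimensions.",
      class = "fretcal_input_error")
  }
  ref <- stacks[[reference_channel]]
  fp <- find_focus_plane(ref, seed_x, seed_y, search_radius_px)
  ref_plane <- stack_plane(ref, fp$z)

  measure_all <- function(roi, apply_fun) {
    vapply(chans, function(ch) {
      apply_fun(stack_plane(stacks[[ch]], fp$z), roi)
    }, numeric(1))
  }

  if (phase == "metaphase") {
    m <- measure_metaphase_cluster(ref_plane, fp$x, fp$y)
    roi <- m$roi
    ints <- measure_all(roi, function(plane, roi) {
      meta_box_corrected(plane, roi$box_origin[["x"]], roi$box_origin[["y"]])
    })
    fit_ok <- TRUE
  } else {
    m <- tryCatch(
      measure_anaphase_cluster(ref_plane, fp$x, fp$y, fit_window_px, mask_sigma),
      fretcal_fit_failed = function(e) NULL
    )
    if (is.null(m)) {
      roi <- list(method = "anaphase_gaussian", fit_failed = TRUE,
                  peak = c(x = fp$x, y = fp$y))
      ints <- setNames(rep(0, 3), chans)
      fit_ok <- FALSE
    } else {
      roi <- m$roi
      ints <- measure_all(roi, anaphase_apply_roi)
      fit_ok <- TRUE
    }
  }
  roi$focus_z <- fp$z
  tibble(
    cell_id = cell_id,
    phase = phase,
    I_donor = ints[["donor"]],
    I_acceptor = ints[["acceptor"]],
    I_fret = ints[["fret"]],
    focus_z = fp$z,
    roi_method = roi$method,
    roi_params = as.character(jsonlite::toJSON(roi, auto_unbox = TRUE, digits = NA)),
    fit_ok = fit_ok
  )
}

#' Quantify many clusters from a clicks table
#'
#' @param cells named list: one entry per cell, each a named list of the
#'   three [channel_stack()]s (as produced by [render_cell()] or
#'   [read_stack()]).
#' @param clicks data frame with columns `cell_id`, `x`, `y`, `phase` (one
#'   row per cluster to quantify; `cell_id` must match `names(cells)`).
#' @param ... passed to [quantify_cell()].
#' @return A tibble with one row per click, same schema as [quantify_cell()].
#' @export
quantify_cells <- function(cells, clicks, ...) {
  stopifnot(is.data.frame(clicks),
            all(c("cell_id", "x", "y", "phase") %in% names(clicks)))
  missing <- setdiff(unique(clicks$cell_id), names(cells))
  if (length(missing) > 0) {
    abort(paste0("No stacks for cell(s): ", paste(missing, collapse = ", ")),
      class = "fretcal_input_error")
  }
  purrr::pmap_dfr(
    clicks[c("cell_id", "x", "y", "phase")],
    function(cell_id, x, y, phase) {
      quantify_cell(cells[[cell_id]], x, y, phase = phase, cell_id = cell_id, ...)
    }
  )
}
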