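#' FRET efficiency from donor quenching
#'
#' FRET quenches the donor: the ratio of the mean donor intensity in a
#' doubly labeled (FRET) strain to the mean donor intensity in a matched
#' donor-only strain, imaged under identical excitation, gives `1 - E`.
#' Because every cluster carries a stereotyped number of molecules, the two
#' population means are directly comparable. The standard deviation of the
#' estimate follows first-order propagation for a ratio of two sample means:
#' `sd(r) = r * sqrt((sem_f / mean_f)^2 + (sem_d / mean_d)^2)`, with sems the
#' standard errors of each mean.
#'
#' @param fret_donor_intensities numeric vector of donor-channel intensities
#'   in the FRET strain.
#' @param donor_only_intensities numeric vector of donor-channel intensities
#'   in the donor-only strain.
#' @param phase optional label (`"metaphase"`/`"anaphase"`) carried through.
#' @return An object of class `efficiency_estimate` with fields
#'   `efficiency`, `sd`, `n_fret`, `n_donor_only`, `phase` and `negative`
#'   (flag; negative efficiencies are reported unclipped, with a warning).
#' @export
efficiency_from_donor_quenching <- function(fret_donor_intensities,
                                            donor_only_intensities,
                                            phase = NA_character_) {
  f <- fret_donor_intensities
  d <- donor_only_intensities
  if (length(f) == 0 || length(d) == 0) {
    abort("Both intensity vectors must be non-empty.", class = "fretcal_input_error")
  }
  if (mean(d) <= 0) {
    abort("Donor-only mean intensity must be positive.", class = "fretcal_input_error")
  }
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  r <- mean(f) / mean(d)
  rel <- sqrt((sem(f) / mean(f))^2 + (sem(d) / mean(d))^2)
  e <- 1 - r
  if (e < 0) warn(sprintf("Negative FRET efficiency (%.4g) reported unclipped.", e))
  structure(
    list(efficiency = e, sd = abs(r) * rel, n_fret = length(f),
         n_donor_only = length(d), phase = phase, negative = e < 0),
    class = "efficiency_estimate"
  )
}

#' @export
print.efficiency_estimate <- function(x, ...) {
  cat(sprintf("<efficiency_estimate: E = %.4g +/- %.3g (n = %d FRET / %d donor-only%s)>\n",
    x$efficiency, x$sd, x$n_fret, x$n_donor_only,
    if (is.na(x$phase)) "" else paste0(", ", x$phase)))
  invisible(x)
}

#' @method tidy efficiency_estimate
#' @export
tidy.efficiency_estimate <- function(x, ...) {
  tibble(efficiency = x$efficiency, sd = x$sd, n_fret = x$n_fret,
         n_donor_only = x$n_donor_only, phase = x$phase)
}

#' Construct a proximity-ratio -> efficiency calibration line
#'
#' `calibration_model()` builds the model from known coefficients (e.g. a
#' published calibration); [fit_calibration()] estimates it from data.
#'
#' @param slope efficiency change per unit proximity ratio.
#' @param intercept efficiency at zero proximity ratio.
#' @param r_squared coefficient of determination of the fit (if known).
#' @param ci95_slope,ci95_intercept length-2 95% confidence intervals.
#' @param n_points number of points behind the fit.
#' @return An object of class `fret_calibration`.
#' @export
calibration_model <- function(slope, intercept, r_squared = NA_real_,
                              ci95_slope = c(NA_real_, NA_real_),
                              ci95_intercept = c(NA_real_, NA_real_),
                              n_points = NA_integer_) {
  stopifnot(is.numeric(slope), is.numeric(intercept))
  structure(
    list(slope = slope, intercept = intercept, r_squared = r_squared,
         ci95_slope = ci95_slope, ci95_intercept = ci95_intercept,
         n_points = as.integer(n_points), fit = NULL),
    class = "fret_calibration"
  )
}

#' Fit the linear calibration between proximity ratio and FRET efficiency
#'
#' Ordinary least squares of efficiency on proximity ratio across the
#' calibration points (one point per strain and cell-cycle phase, typically).
#' The line lets routine, easy-to-measure proximity ratios be converted to
#' absolute FRET efficiencies. An inverse-variance weighted fit is available
#' when per-point standard deviations are supplied.
#'
#' @param points data frame with columns `proximity_ratio` and `efficiency`;
#'   an optional `sd` column enables weighting.
#' @param weighted if `TRUE`, weight each point by `1 / sd^2`.
#' @return A `fret_calibration` object; inspect with [tidy()], [glance()],
#'   [autoplot()], and apply with [efficiency_from_proximity_ratio()].
#' @examples
#' pts <- tibble::tibble(proximity_ratio = c(0.1, 0.8, 1.7),
#'                       efficiency = c(0.015, 0.110, 0.232))
#' fit_calibration(pts)
#' @export
fit_calibration <- function(points, weighted = FALSE) {
  stopifnot(is.data.frame(points))
  need <- c("proximity_ratio", "efficiency")
  if (!all(need %in% names(points))) {
    abort("`points` needs columns proximity_ratio and efficiency.",
      class = "fretcal_input_error")
  }
  pts <- points[complete.cases(points[need]), , drop = FALSE]
  if (nrow(pts) < 2) {
    abort("At least two calibration points are required.",
      class = "fretcal_input_error")
  }
  if (length(unique(pts$proximity_ratio)) < 2) {
    abort("All proximity ratios are equal: calibration line is singular.",
      class = "fretcal_singular_fit")
  }
  w <- NULL
  if (weighted) {
    if (!"sd" %in% names(pts) || any(pts$sd <= 0)) {
      abort("Weighted fit needs a positive `sd` column.", class = "fretcal_input_error")
    }
    w <- 1 / pts$sd^2
  }
  fit <- lm(efficiency ~ proximity_ratio, data = pts, weights = w)
  co <- coef(fit)
  n <- nrow(pts)
  ci <- if (n > 2) suppressWarnings(confint(fit, level = 0.95)) else
    matrix(c(-Inf, -Inf, Inf, Inf), 2, 2,
           dimnames = list(names(co), c("2.5 %", "97.5 %")))
  out <- calibration_model(
    slope = co[["proximity_ratio"]],
    intercept = co[["(Intercept)"]],
    r_squared = summary(fit)$r.squared,
    ci95_slope = unname(ci["proximity_ratio", ]),
    ci95_intercept = unname(ci["(Intercept)", ]),
    n_points = n
  )
  out$fit <- fit
  out
}

#' @export
print.fret_calibration <- function(x, ...) {
  cat(sprintf(
    "<fret_calibration: E = %.4g * PR + %.4g (R^2 = %s, n = %s)>\n",
    x$slope, x$intercept,
    if (is.na(x$r_squared)) "?" else sprintf("%.3f", x$r_squared),
    if (is.na(x$n_points)) "?" else x$n_points))
  invisible(x)
}

#' @method tidy fret_calibration
#' @export
tidy.fret_calibration <- function(x, ...) {
  tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    conf.low = c(x$ci95_intercept[1], x$ci95_slope[1]),
    conf.high = c(x$ci95_intercept[2], x$ci95_slope[2])
  )
}

#' @method glance fret_calibration
#' @export
glance.fret_calibration <- function(x, ...) {
  tibble(r.squared = x$r_squared, n = x$n_points)
}

#' Convert a proximity ratio to FRET efficiency through a calibration
#'
#' @param pr proximity ratio(s).
#' @param model a `fret_calibration`.
#' @return Efficiencies `slope * pr + intercept`. Values outside `[0, 1)`
#'   are flagged with a warning but not clipped.
#' @export
efficiency_from_proximity_ratio <- function(pr, model) {
  stopifnot(inherits(model, "fret_calibration"), is.numeric(pr))
  e <- model$slope * pr + model$intercept
  if (any(e < 0 | e >= 1)) {
    warn("Some converted efficiencies fall outside [0, 1); reported unclipped.")
  }
  e
}

#' End-to-end calibration from measurement tables
#'
#' Runs the full workflow: estimate spectral coefficients from the
#' single-label controls, compute per-cluster proximity ratios in the FRET
#' strains, collapse to one (mean PR, donor-quenching E) point per
#' strain-phase group, and fit the calibration line.
#'
#' @param measurements FRET-strain measurement table with columns `strain`,
#'   `phase`, `I_donor`, `I_acceptor`, `I_fret`.
#' @param donor_only,acceptor_only single-label control measurement tables
#'   (`donor_only` additionally provides the unquenched donor reference and
#'   may carry a `phase` column matched against the FRET strains).
#' @return A list with elements `coefficients` ([spectral_coefficients()]),
#'   `points` (tibble of per-group PR and E) and `model`
#'   (`fret_calibration`).
#' @export
build_calibration <- function(measurements, donor_only, acceptor_only) {
  stopifnot(is.data.frame(measurements))
  if (!"strain" %in% names(measurements)) {
    abort("`measurements` needs a `strain` column.", class = "fretcal_input_error")
  }
  coefs <- estimate_spectral_coefficients(donor_only, acceptor_only)
  q <- add_fret_quantification(measurements, coefs)
  groups <- if ("phase" %in% names(q)) c("strain", "phase") else "strain"
  pts <- q |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(
      pr_sd = sd(.data$proximity_ratio),
      proximity_ratio = mean(.data$proximity_ratio),
      .donor = list(.data$I_donor),
      n = dplyr::n(),
      .groups = "drop"
    )
  ref_for <- function(ph) {
    if ("phase" %in% names(donor_only) && !is.na(ph)) {
      sub <- donor_only$I_donor[donor_only$phase == ph]
      if (length(sub) > 0) return(sub)
    }
    donor_only$I_donor
  }
  est <- purrr::pmap(
    list(pts$.donor, if ("phase" %in% names(pts)) pts$phase else
      rep(NA_character_, nrow(pts))),
    function(dvec, ph) efficiency_from_donor_quenching(dvec, ref_for(ph), phase = ph)
  )
  pts$efficiency <- vapply(est, function(e) e$efficiency, numeric(1))
  pts$sd <- vapply(est, function(e) e$sd, numeric(1))
  pts$.donor <- NULL
  model <- fit_calibration(pts)
  list(coefficients = coefs, points = pts, model = model)
}

#' @method autoplot fret_calibration
#' @export
autoplot.fret_calibration <- function(object, points = NULL, ...) {
  p <- ggplot2::ggplot() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept) +
    ggplot2::labs(x = "Proximity ratio", y = "FRET efficiency") +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_pointrange(
      data = points,
      ggplot2::aes(x = .data$proximity_ratio, y = .data$efficiency,
                   ymin = .data$efficiency - .data$sd,
                   ymax = .data$efficiency + .data$sd))
  }
  p
}
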