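#' Spectral contamination coefficients for the FRET channel
#'
#' The FRET channel contains, besides true sensitized emission, two
#' contaminations: donor fluorescence bleeding through into the acceptor
#' emission window (`alpha`, as a fraction of the donor-channel signal) and
#' acceptor fluorescence from direct excitation at the donor wavelength
#' (`beta`, as a fraction of the acceptor-channel signal). For the
#' GFP(S65T)/mCherry pair on the reference setup these are 5.8% and 6.1%
#' (see [gfp_mcherry_defaults()]).
#'
#' @param alpha donor bleed-through fraction, in `[0, 1)`.
#' @param beta acceptor cross-excitation fraction, in `[0, 1)`.
#' @param alpha_sem,beta_sem standard errors of the two fractions.
#' @param n_donor,n_acceptor number of control clusters behind each estimate.
#' @return An object of class `spectral_coefficients`.
#' @export
spectral_coefficients <- function(alpha, beta, alpha_sem = 0, beta_sem = 0,
                                  n_donor = NA_integer_, n_acceptor = NA_integer_) {
  stopifnot(alpha >= 0, alpha < 1, beta >= 0, beta < 1,
            alpha_sem >= 0, beta_sem >= 0)
  structure(
    list(alpha = alpha, beta = beta, alpha_sem = alpha_sem, beta_sem = beta_sem,
         n_donor = n_donor, n_acceptor = n_acceptor),
    class = "spectral_coefficients"
  )
}

#' @export
print.spectral_coefficients <- function(x, ...) {
  cat(sprintf(
    "<spectral_coefficients: alpha = %.4g +/- %.2g (n = %s), beta = %.4g +/- %.2g (n = %s)>\n",
    x$alpha, x$alpha_sem, x$n_donor, x$beta, x$beta_sem, x$n_acceptor))
  invisible(x)
}

#' @method tidy spectral_coefficients
#' @export
tidy.spectral_coefficients <- function(x, ...) {
  tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    std.error = c(x$alpha_sem, x$beta_sem),
    n = c(x$n_donor, x$n_acceptor)
  )
}

#' Estimate bleed-through and cross-excitation from single-label controls
#'
#' Donor-only cells carry no acceptor, so their entire FRET-channel signal
#' is donor bleed-through; likewise acceptor-only cells isolate
#' cross-excitation. Each coefficient is the mean of the per-cluster ratio
#' (FRET-channel over own-channel intensity), with its standard error of the
#' mean. Clusters with a non-positive own-channel denominator are excluded
#' with a warning.
#'
#' @param donor_only,acceptor_only data frames of control-cell measurements
#'   with columns `I_donor`, `I_acceptor`, `I_fret` (e.g. from
#'   [quantify_cells()]).
#' @return A [spectral_coefficients()] object.
#' @export
estimate_spectral_coefficients <- function(donor_only, acceptor_only) {
  ratio_mean <- function(df, denom_col, label) {
    if (!is.data.frame(df) || nrow(df) == 0) {
      abort(sprintf("`%s` must be a non-empty data frame.", label),
        class = "fretcal_input_error")
    }
    denom <- df[[denom_col]]
    bad <- denom <= 0
    if (any(bad)) {
      warn(sprintf("Excluding %d %s cluster(s) with non-positive %s.",
        sum(bad), label, denom_col))
      df <- df[!bad, , drop = FALSE]
      denom <- denom[!bad]
    }
    if (nrow(df) == 0) {
      abort(sprintf("No usable clusters in `%s`.", label),
        class = "fretcal_input_error")
    }
    r <- df$I_fret / denom
    list(mean = mean(r), sem = if (length(r) > 1) sd(r) / sqrt(length(r)) else 0,
         n = length(r))
  }
  a <- ratio_mean(donor_only, "I_donor", "donor_only")
  b <- ratio_mean(acceptor_only, "I_acceptor", "acceptor_only")
  spectral_coefficients(a$mean, b$mean, a$sem, b$sem, a$n, b$n)
}

#' Sensitized emission and proximity ratio per cluster
#'
#' `add_fret_quantification()` appends three columns to a measurement table:
#'
#' * `sensitized_emission`: the FRET-channel signal with the two estimated
#'   contaminations removed, `I_fret - alpha * I_donor - beta * I_acceptor`.
#'   Negative values are kept, so that population averages stay unbiased.
#' * `contamination`: the summed contamination `alpha * I_donor +
#'   beta * I_acceptor` used as the normalization.
#' * `proximity_ratio`: sensitized emission divided by the contamination.
#'   This normalization makes the ratio invariant under proportional changes
#'   of integration time or excitation intensity, and equals the classical
#'   FRET_R metric minus one.
#'
#' @param measurements data frame with `I_donor`, `I_acceptor`, `I_fret`.
#' @param coefficients a [spectral_coefficients()] object.
#' @return The input tibble with `sensitized_emission`, `contamination` and
#'   `proximity_ratio` columns added.
#' @examples
#' m <- tibble::tibble(I_donor = 500, I_acceptor = 500, I_fret = 100)
#' add_fret_quantification(m, spectral_coefficients(0.058, 0.061))
#' @export
add_fret_quantification <- function(measurements, coefficients) {
  stopifnot(is.data.frame(measurements),
            inherits(coefficients, "spectral_coefficients"))
  need <- c("I_donor", "I_acceptor", "I_fret")
  if (!all(need %in% names(measurements))) {
    abort("`measurements` needs columns I_donor, I_acceptor, I_fret.",
      class = "fretcal_input_error")
  }
  out <- as_tibble(measurements)
  out$contamination <- coefficients$alpha * out$I_donor +
    coefficients$beta * out$I_acceptor
  out$sensitized_emission <- out$I_fret - out$contamination
  if (any(out$contamination <= 0)) {
    i <- which(out$contamination <= 0)[1]
    id <- if ("cell_id" %in% names(out)) out$cell_id[i] else paste("row", i)
    abort(sprintf("Proximity ratio undefined for cluster %s: contamination <= 0.", id),
      class = "fretcal_undefined_ratio")
  }
  out$proximity_ratio <- out$sensitized_emission / out$contamination
  out
}

#' @rdname add_fret_quantification
#' @export
compute_sensitized_emission <- function(measurements, coefficients) {
  stopifnot(is.data.frame(measurements),
            inherits(coefficients, "spectral_coefficients"))
  out <- as_tibble(measurements)
  out$sensitized_emission <- out$I_fret - coefficients$alpha * out$I_donor -
    coefficients$beta * out$I_acceptor
  out
}
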