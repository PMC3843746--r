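#' Parameters for efficiency-to-distance conversion
#'
#' The Förster radius `r0_nm` is the donor-acceptor separation at which
#' transfer efficiency is 50% (about 5 nm for GFP-mCherry). The orientation
#' factor `kappa_squared = 0.66` (2/3) is the isotropic-rotation assumption
#' under which that radius holds; it is recorded for provenance only and no
#' anisotropy computation is performed. `maturation_fraction` is the
#' fraction of acceptor proteins that form a functional chromophore: dark
#' acceptors dilute the apparent population-average efficiency, so the true
#' per-pair efficiency is the apparent one divided by this fraction.
#'
#' @param r0_nm Förster radius in nm (> 0).
#' @param maturation_fraction acceptor maturation efficiency in `(0, 1]`.
#' @param kappa_squared documented orientation-factor assumption.
#' @return An object of class `forster_params`.
#' @export
forster_params <- function(r0_nm = 5, maturation_fraction = 1,
                           kappa_squared = 0.66) {
  stopifnot(r0_nm > 0, maturation_fraction > 0, maturation_fraction <= 1)
  structure(list(r0_nm = r0_nm, maturation_fraction = maturation_fraction,
                 kappa_squared = kappa_squared),
            class = "forster_params")
}

#' @export
print.forster_params <- function(x, ...) {
  cat(sprintf(
    "<forster_params: R0 = %g nm, maturation = %g, kappa^2 = %g (assumed)>\n",
    x$r0_nm, x$maturation_fraction, x$kappa_squared))
  invisible(x)
}

#' Donor-acceptor separation from FRET efficiency
#'
#' Inverts `E = 1 / (1 + (R/R0)^6)` to `R = R0 * ((1 - E) / E)^(1/6)`.
#'
#' @param efficiency FRET efficiency, strictly inside `(0, 1)` (vectorized).
#' @param params a [forster_params()], or anything with an `r0_nm` field.
#' @return Separation(s) in nm.
#' @examples
#' forster_distance(0.5)           # exactly R0
#' forster_distance(0.18)          # 6.44 nm at R0 = 5
#' @export
forster_distance <- function(efficiency, params = forster_params()) {
  if (any(efficiency <= 0 | efficiency >= 1)) {
    abort("Efficiency must lie strictly inside (0, 1) for distance conversion.",
      class = "fretcal_domain_error")
  }
  params$r0_nm * ((1 - efficiency) / efficiency)^(1 / 6)
}

#' FRET efficiency at a given donor-acceptor separation
#'
#' `E = 1 / (1 + (R/R0)^6)`; the exact inverse of [forster_distance()].
#'
#' @param r_nm separation(s) in nm (> 0).
#' @inheritParams forster_distance
#' @return Efficiency values in `(0, 1)`.
#' @export
forster_efficiency <- function(r_nm, params = forster_params()) {
  if (any(r_nm <= 0)) {
    abort("Separation must be positive.", class = "fretcal_domain_error")
  }
  1 / (1 + (r_nm / params$r0_nm)^6)
}

#' Correct an apparent efficiency for incomplete acceptor maturation
#'
#' With a fraction `m` of acceptors fluorescent, a donor population whose
#' true per-pair efficiency is `E` shows an apparent population efficiency
#' of only `m * E` (donors facing dark acceptors are not quenched). The
#' correction is therefore a division: `E_true = E_apparent / m`.
#'
#' @param e_apparent apparent efficiency (>= 0, vectorized).
#' @inheritParams forster_distance
#' @return Corrected efficiencies; an error if any corrected value
#'   reaches 1.
#' @examples
#' correct_for_maturation(0.059, forster_params(maturation_fraction = 1/3))
#' @export
correct_for_maturation <- function(e_apparent, params = forster_params()) {
  if (any(e_apparent < 0)) {
    abort("Apparent efficiency must be non-negative.", class = "fretcal_domain_error")
  }
  e <- e_apparent / params$maturation_fraction
  if (any(e >= 1)) {
    abort("Maturation-corrected efficiency reaches 1; check maturation_fraction.",
      class = "fretcal_domain_error")
  }
  e
}
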