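#' Built-in parameter profile for the GFP(S65T)/mCherry FRET pair
#'
#' The coefficient set measured for C-terminal GFP/mCherry fusions on the
#' reference epifluorescence setup (budding-yeast kinetochore calibration
#' strains): donor bleed-through alpha = 5.8%, acceptor cross-excitation
#' beta = 6.1%, calibration line E = 0.1355 * PR + 0.002, Förster radius
#' 5 nm, and an acceptor maturation fraction of 0.30 as estimated from
#' lifetime measurements. Every element can be overridden.
#'
#' @param maturation_fraction acceptor maturation efficiency to embed in the
#'   Förster parameters (default 0.30).
#' @return A named list with elements `coefficients`
#'   ([spectral_coefficients()]), `calibration` (`fret_calibration`) and
#'   `forster` ([forster_params()]).
#' @examples
#' prof <- gfp_mcherry_defaults()
#' e <- efficiency_from_proximity_ratio(0.43, prof$calibration)
#' forster_distance(correct_for_maturation(e, prof$forster), prof$forster)
#' @export
gfp_mcherry_defaults <- function(maturation_fraction = 0.30) {
  list(
    coefficients = spectral_coefficients(
      alpha = 0.058, beta = 0.061,
      alpha_sem = 0.0001, beta_sem = 0.0002
    ),
    calibration = calibration_model(slope = 0.1355, intercept = 0.002,
                                    r_squared = 0.98),
    forster = forster_params(r0_nm = 5, maturation_fraction = maturation_fraction)
  )
}
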