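#' Ground-truth parameters for one synthetic cell
#'
#' Describes a dividing yeast-like cell carrying two fluorescent clusters
#' (e.g. sister-kinetochore clusters) of `n_pairs` donor/acceptor-labeled
#' molecules each. Per-cluster brightness multipliers emulate the measured
#' cluster-to-cluster intensity variability (sd 0.114 for the donor, 0.166
#' for the acceptor, the latter dominated by variable acceptor maturation);
#' spectral mixing into the FRET channel uses the bleed-through and
#' cross-excitation fractions; clusters are rendered as 3-D Gaussian spots
#' on the camera grid with Poisson shot noise, Gaussian read noise and a
#' constant camera offset.
#'
#' @param phase `"metaphase"` or `"anaphase"`; sets the default cluster
#'   separation (800 nm vs 4500 nm) and the photometry used downstream.
#' @param separation_nm distance between the two clusters (default by
#'   phase).
#' @param n_pairs labeled molecules per cluster (default 128, i.e. 16
#'   kinetochores x 8 molecules).
#' @param brightness_donor,brightness_acceptor integrated counts per
#'   fluorophore in its own channel.
#' @param e_true per-pair FRET efficiency transferred when the acceptor is
#'   fluorescent.
#' @param maturation_fraction probability that an acceptor has a functional
#'   chromophore.
#' @param sigma_donor,sigma_acceptor sd of the per-cluster brightness
#'   multipliers (truncated normal, mean 1, floored at 0).
#' @param alpha,beta spectral contamination fractions (see
#'   [spectral_coefficients()]).
#' @param gamma sensitized-detection factor: FRET-channel counts produced
#'   per donor-channel count lost to transfer (default 1).
#' @param has_donor,has_acceptor set `FALSE` for single-label control
#'   strains.
#' @param psf_sigma_xy_nm,psf_sigma_z_nm Gaussian PSF widths.
#' @param pixel_size_nm,z_step_nm camera sampling (160 / 200 nm).
#' @param camera_offset,read_noise_sd camera baseline and Gaussian read
#'   noise (counts).
#' @return A `cell_truth` list of generator parameters.
#' @export
cell_truth <- function(phase = c("metaphase", "anaphase"),
                       separation_nm = NULL, n_pairs = 128,
                       brightness_donor = 2000, brightness_acceptor = 2000,
                       e_true = 0, maturation_fraction = 1,
                       sigma_donor = 0.114, sigma_acceptor = 0.166,
                       alpha = 0.058, beta = 0.061, gamma = 1,
                       has_donor = TRUE, has_acceptor = TRUE,
                       psf_sigma_xy_nm = 110, psf_sigma_z_nm = 300,
                       pixel_size_nm = 160, z_step_nm = 200,
                       camera_offset = 100, read_noise_sd = 2) {
  phase <- match.arg(phase)
  if (is.null(separation_nm)) {
    separation_nm <- if (phase == "metaphase") 800 else 4500
  }
  stopifnot(n_pairs >= 1, e_true >= 0, e_true < 1,
            maturation_fraction >= 0, maturation_fraction <= 1,
            brightness_donor >= 0, brightness_acceptor >= 0)
  structure(
    list(phase = phase, separation_nm = separation_nm,
         n_pairs = as.integer(n_pairs),
         brightness_donor = brightness_donor,
         brightness_acceptor = brightness_acceptor,
         e_true = e_true, maturation_fraction = maturation_fraction,
         sigma_donor = sigma_donor, sigma_acceptor = sigma_acceptor,
         alpha = alpha, beta = beta, gamma = gamma,
         has_donor = has_donor, has_acceptor = has_acceptor,
         psf_sigma_xy_nm = psf_sigma_xy_nm, psf_sigma_z_nm = psf_sigma_z_nm,
         pixel_size_nm = pixel_size_nm, z_step_nm = z_step_nm,
         camera_offset = camera_offset, read_noise_sd = read_noise_sd),
    class = "cell_truth"
  )
}

#' Expected channel intensities for synthetic clusters
#'
#' The photophysical closure of the spectral-correction model. For each
#' cluster: all donors are fluorescent; the number of fluorescent acceptors
#' is Binomial(`n_pairs`, `maturation_fraction`), realizing a paired-donor
#' fraction `f`; then
#'
#' * `I_donor = g_D * B_D * N_D * (1 - e_true * f)` (quenching),
#' * true sensitized emission `SE = g_D * B_D * N_D * e_true * f * gamma`,
#' * `I_acceptor = g_A * B_A * N_A_fluor`,
#' * `I_fret = SE + alpha * I_donor + beta * I_acceptor`.
#'
#' So a no-FRET cluster has zero sensitized emission after correction, and
#' incomplete maturation scales the apparent donor-quenching efficiency by
#' `f` — exactly the effect [correct_for_maturation()] undoes.
#'
#' @param truth a [cell_truth()].
#' @param n_clusters clusters to draw (default 2).
#' @param noiseless if `TRUE`, fix brightness multipliers at 1 and the
#'   fluorescent-acceptor count at its expectation.
#' @return A tibble with one row per cluster: multipliers, realized counts
#'   and the three expected channel intensities.
#' @export
channel_intensities <- function(truth, n_clusters = 2, noiseless = FALSE) {
  stopifnot(inherits(truth, "cell_truth"))
  n <- n_clusters
  g_d <- if (noiseless) rep(1, n) else pmax(0, rnorm(n, 1, truth$sigma_donor))
  g_a <- if (noiseless) rep(1, n) else pmax(0, rnorm(n, 1, truth$sigma_acceptor))
  n_d <- if (truth$has_donor) rep(truth$n_pairs, n) else rep(0L, n)
  n_a <- if (!truth$has_acceptor) rep(0L, n) else if (noiseless) {
    rep(round(truth$maturation_fraction * truth$n_pairs), n)
  } else {
    rbinom(n, truth$n_pairs, truth$maturation_fraction)
  }
  f <- n_a / truth$n_pairs
  i_donor <- g_d * truth$brightness_donor * n_d * (1 - truth$e_true * f)
  se_true <- g_d * truth$brightness_donor * n_d * truth$e_true * f * truth$gamma
  i_acceptor <- g_a * truth$brightness_acceptor * n_a
  tibble(
    cluster = seq_len(n),
    g_donor = g_d, g_acceptor = g_a,
    n_donor_fluor = n_d, n_acceptor_fluor = n_a, f_paired = f,
    I_donor_true = i_donor,
    I_acceptor_true = i_acceptor,
    sensitized_true = se_true,
    I_fret_true = se_true + truth$alpha * i_donor + truth$beta * i_acceptor
  )
}

# integral of a unit 1-D Gaussian over each pixel [i - 0.5, i + 0.5]
pixel_weights <- function(n, center, sigma) {
  diff(stats::pnorm(seq(0.5, n + 0.5), center, sigma))
}

#' Render a synthetic cell as three channel stacks
#'
#' Places the cell's two clusters (separated along x by the phase-dependent
#' distance) as 3-D Gaussian spots sampled on the camera grid, with
#' independent sub-pixel jitter per cell, and applies per-voxel Poisson
#' shot noise plus camera offset and Gaussian read noise. The PSF and
#' geometry are identical across channels, so ratio quantities (proximity
#' ratio, donor quenching) are insensitive to the single-plane mask
#' truncation of the photometry.
#'
#' @param truth a [cell_truth()].
#' @param cell_id identifier propagated to the truth rows.
#' @param noise if `FALSE`, skip shot/read noise and the camera offset
#'   (voxels are the noiseless expected signal).
#' @param margin_px lateral margin around the cluster positions.
#' @param n_planes number of z planes (default 9).
#' @return A list: `stacks` (named list of three [channel_stack()]s),
#'   `clusters` (truth tibble with click coordinates and expected
#'   intensities), `clicks` (tibble ready for [quantify_cells()]).
#' @export
render_cell <- function(truth, cell_id = "cell", noise = TRUE,
                        margin_px = 10, n_planes = 9) {
  stopifnot(inherits(truth, "cell_truth"))
  ci <- channel_intensities(truth, n_clusters = 2, noiseless = FALSE)
  sep_px <- truth$separation_nm / truth$pixel_size_nm
  nx <- as.integer(ceiling(sep_px) + 2 * margin_px)
  ny <- as.integer(2 * margin_px + 1)
  nz <- as.integer(n_planes)
  x1 <- margin_px + runif(1, -0.5, 0.5)
  x2 <- x1 + sep_px
  y0 <- (ny + 1) / 2 + runif(1, -0.5, 0.5)
  z0 <- (nz + 1) / 2 + runif(1, -0.5, 0.5)
  sxy <- truth$psf_sigma_xy_nm / truth$pixel_size_nm
  sz <- truth$psf_sigma_z_nm / truth$z_step_nm

  wy <- pixel_weights(ny, y0, sxy)
  wz <- pixel_weights(nz, z0, sz)
  wx1 <- pixel_weights(nx, x1, sxy)
  wx2 <- pixel_weights(nx, x2, sxy)
  spot1 <- (wy %o% wx1) %o% wz
  spot2 <- (wy %o% wx2) %o% wz

  render_channel <- function(i1, i2, label) {
    signal <- i1 * spot1 + i2 * spot2
    vox <- if (noise) {
      pmax(0, rpois(length(signal), signal) + truth$camera_offset +
             rnorm(length(signal), 0, truth$read_noise_sd))
    } else signal
    channel_stack(array(vox, dim = c(ny, nx, nz)),
                  pixel_size_nm = truth$pixel_size_nm,
                  z_step_nm = truth$z_step_nm, channel = label)
  }
  stacks <- list(
    donor = render_channel(ci$I_donor_true[1], ci$I_donor_true[2], "donor"),
    acceptor = render_channel(ci$I_acceptor_true[1], ci$I_acceptor_true[2],
                              "acceptor"),
    fret = render_channel(ci$I_fret_true[1], ci$I_fret_true[2], "fret")
  )
  clusters <- ci
  clusters$cell_id <- cell_id
  clusters$phase <- truth$phase
  clusters$click_x <- c(round(x1), round(x2))
  clusters$click_y <- rep(round(y0), 2)
  clusters$center_z <- z0
  list(
    stacks = stacks,
    clusters = clusters,
    clicks = tibble(cell_id = cell_id, cluster = 1:2,
                    x = c(round(x1), round(x2)), y = rep(round(y0), 2),
                    phase = truth$phase)
  )
}

#' Generate a full synthetic calibration experiment
#'
#' Emulates the three-strain calibration design plus the two single-label
#' control strains: `n_strains` FRET strains at the given true efficiencies,
#' a donor-only strain (no acceptor; provides both the bleed-through
#' controls and the unquenched donor reference) and an acceptor-only strain.
#' Every cell is rendered as three channel stacks.
#'
#' @param e_true named vector of per-pair efficiencies for the FRET strains
#'   (defaults emulate separations spanning the usable FRET range).
#' @param n_cells_fret cells per FRET strain.
#' @param n_cells_controls cells per control strain.
#' @param truth base [cell_truth()] shared by all strains (its `e_true`,
#'   `has_donor`, `has_acceptor` are overridden per strain).
#' @param seed integer seed (local to this call), or `NULL`.
#' @return A list: `cells` (named list of stack lists), `clicks` (tibble
#'   with `cell_id`, `cluster`, `x`, `y`, `phase`, `strain`, `type`),
#'   `truth` (per-cluster truth tibble) and `params` (the base truth).
#' @export
generate_calibration_dataset <- function(e_true = c(strain_low = 0.02,
                                                    strain_mid = 0.10,
                                                    strain_high = 0.25),
                                         n_cells_fret = 100,
                                         n_cells_controls = 100,
                                         truth = cell_truth(),
                                         seed = NULL) {
  stopifnot(all(e_true >= 0), all(e_true < 1))
  if (is.null(names(e_true))) {
    names(e_true) <- paste0("strain_", seq_along(e_true))
  }
  plan <- dplyr::bind_rows(
    tibble(strain = "donor_only", type = "donor_only", e = 0,
           n = n_cells_controls),
    tibble(strain = "acceptor_only", type = "acceptor_only", e = 0,
           n = n_cells_controls),
    tibble(strain = names(e_true), type = "fret", e = unname(e_true),
           n = n_cells_fret)
  )
  with_local_seed(seed, {
    cells <- list()
    clicks <- list()
    truth_rows <- list()
    for (s in seq_len(nrow(plan))) {
      tr <- truth
      tr$e_true <- plan$e[s]
      tr$has_donor <- plan$type[s] != "acceptor_only"
      tr$has_acceptor <- plan$type[s] == "fret" ||
        plan$type[s] == "acceptor_only"
      for (i in seq_len(plan$n[s])) {
        id <- sprintf("%s_%04d", plan$strain[s], i)
        cell <- render_cell(tr, cell_id = id)
        cells[[id]] <- cell$stacks
        ck <- cell$clicks
        ck$strain <- plan$strain[s]
        ck$type <- plan$type[s]
        ck$e_true <- plan$e[s]
        clicks[[id]] <- ck
        tru <- cell$clusters
        tru$strain <- plan$strain[s]
        tru$type <- plan$type[s]
        tru$e_true <- plan$e[s]
        truth_rows[[id]] <- tru
      }
    }
    list(cells = cells,
         clicks = dplyr::bind_rows(clicks),
         truth = dplyr::bind_rows(truth_rows),
         params = truth)
  })
}

#' Calibration line implied by a synthetic truth table
#'
#' Applies the calibration arithmetic to the noiseless truth intensities of
#' a generated dataset (the conditional expectations of every measurement,
#' given the drawn brightness multipliers and maturation counts): exact
#' spectral coefficients, per-cluster proximity ratios, per-strain
#' donor-quenching efficiencies, and the OLS line through the per-strain
#' points. This is the slope a perfect measurement of the rendered dataset
#' would recover, the natural ground truth for pipeline-recovery tests.
#'
#' @param truth the `truth` tibble of [generate_calibration_dataset()].
#' @param params the base [cell_truth()] of the dataset.
#' @return A list: `points` (per-strain tibble), `slope`, `intercept`.
#' @export
implied_calibration <- function(truth, params) {
  fret <- truth[truth$type == "fret", ]
  donor_ref <- truth$I_donor_true[truth$type == "donor_only"]
  contamination <- params$alpha * fret$I_donor_true +
    params$beta * fret$I_acceptor_true
  fret$pr0 <- fret$sensitized_true / contamination
  pts <- fret |>
    dplyr::group_by(.data$strain) |>
    dplyr::summarise(
      proximity_ratio = mean(.data$pr0),
      efficiency = 1 - mean(.data$I_donor_true) / mean(donor_ref),
      .groups = "drop"
    )
  co <- coef(lm(efficiency ~ proximity_ratio, data = pts))
  list(points = pts, slope = co[["proximity_ratio"]],
       intercept = co[["(Intercept)"]])
}

#' Quantify every cluster of a synthetic dataset
#'
#' Convenience wrapper running [quantify_cells()] on a
#' [generate_calibration_dataset()] result and carrying the strain labels
#' through.
#'
#' @param dataset result of [generate_calibration_dataset()].
#' @param ... passed to [quantify_cell()].
#' @return Measurement tibble with `strain`, `type` and `e_true` columns.
#' @export
quantify_dataset <- function(dataset, ...) {
  clicks <- dataset$clicks
  # single-label acceptor cells carry no donor signal: focus and ROI must be
  # defined on the acceptor channel there
  acc <- clicks$type == "acceptor_only"
  parts <- list()
  if (any(!acc)) {
    m <- quantify_cells(dataset$cells, clicks[!acc, ], ...)
    parts[[1]] <- dplyr::bind_cols(m, clicks[!acc, c("strain", "type", "e_true")])
  }
  if (any(acc)) {
    m <- quantify_cells(dataset$cells, clicks[acc, ],
                        reference_channel = "acceptor", ...)
    parts[[2]] <- dplyr::bind_cols(m, clicks[acc, c("strain", "type", "e_true")])
  }
  dplyr::bind_rows(parts)
}

#' Sample a synthetic TCSPC decay histogram
#'
#' Photon arrival times are the sum of an instrument-response time (Gaussian
#' of the stated center and width) and an exponential decay time, with the
#' emitting component drawn with probability proportional to
#' `amplitude * lifetime` (the photon share of each component of an
#' amplitude-parameterized multi-exponential). Photons outside the
#' measurement window are discarded; the returned IRF is the same Gaussian
#' discretized on the histogram binning.
#'
#' @param amplitudes,lifetimes decay components (amplitudes in relative
#'   units, lifetimes in ns).
#' @param n_photons photons to sample (before window truncation).
#' @param irf_center_ns,irf_width_ns Gaussian IRF position and sd;
#'   `irf_width_ns = 0` gives pure exponential sampling from
#'   `irf_center_ns`.
#' @param t_max_ns measurement window (default 12.5 ns, a ~80 MHz
#'   repetition period).
#' @param n_bins histogram bins (default 256).
#' @param seed integer seed (local), or `NULL`.
#' @return A list: `histogram` ([decay_histogram()]) and `irf`
#'   ([instrument_response()]).
#' @export
generate_decay <- function(amplitudes, lifetimes, n_photons = 1e5,
                           irf_center_ns = 1, irf_width_ns = 0.1,
                           t_max_ns = 12.5, n_bins = 256, seed = NULL) {
  stopifnot(length(amplitudes) == length(lifetimes),
            all(amplitudes >= 0), all(lifetimes > 0), n_photons >= 1)
  edges <- seq(0, t_max_ns, length.out = n_bins + 1)
  with_local_seed(seed, {
    share <- amplitudes * lifetimes
    comp <- sample.int(length(amplitudes), n_photons, replace = TRUE,
                       prob = share / sum(share))
    t0 <- if (irf_width_ns > 0) {
      rnorm(n_photons, irf_center_ns, irf_width_ns)
    } else rep(irf_center_ns, n_photons)
    t <- t0 + rexp(n_photons, rate = 1 / lifetimes[comp])
    t <- t[t >= 0 & t < t_max_ns]
    counts <- tabulate(findInterval(t, edges), nbins = n_bins)
    list(
      histogram = decay_histogram(edges, counts),
      irf = gaussian_irf(edges, irf_center_ns, irf_width_ns)
    )
  })
}
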