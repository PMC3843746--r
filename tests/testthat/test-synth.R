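test_that("generator intensities close algebraically with the correction model", {
  # no FRET: zero sensitized emission, zero proximity ratio (noiseless)
  tr0 <- cell_truth(e_true = 0)
  ci0 <- channel_intensities(tr0, noiseless = TRUE)
  co <- spectral_coefficients(tr0$alpha, tr0$beta)
  q0 <- add_fret_quantification(
    dplyr::rename(ci0, I_donor = I_donor_true, I_acceptor = I_acceptor_true,
                  I_fret = I_fret_true), co)
  expect_equal(q0$sensitized_emission, c(0, 0))
  expect_equal(q0$proximity_ratio, c(0, 0))

  # full maturation at e_true = 0.18: donor quenching reads 0.18 exactly
  tr <- cell_truth(e_true = 0.18, maturation_fraction = 1)
  ci <- channel_intensities(tr, noiseless = TRUE)
  ref <- channel_intensities(cell_truth(e_true = 0), noiseless = TRUE)
  e <- efficiency_from_donor_quenching(ci$I_donor_true, ref$I_donor_true)
  expect_equal(e$efficiency, 0.18)

  # 25% maturation: apparent E = 0.18 * 0.25, restored by the correction
  trm <- cell_truth(e_true = 0.18, maturation_fraction = 0.25, n_pairs = 128)
  cim <- channel_intensities(trm, noiseless = TRUE)
  em <- efficiency_from_donor_quenching(cim$I_donor_true, ref$I_donor_true)
  expect_equal(em$efficiency, 0.18 * 0.25)
  expect_equal(
    correct_for_maturation(em$efficiency,
                           forster_params(maturation_fraction = 0.25)),
    0.18)
})

test_that("doubling donor brightness doubles the donor spot mass only", {
  t1 <- cell_truth(); t2 <- cell_truth(brightness_donor = 2 * t1$brightness_donor)
  set.seed(5); c1 <- channel_intensities(t1, noiseless = TRUE)
  set.seed(5); c2 <- channel_intensities(t2, noiseless = TRUE)
  expect_equal(c2$I_donor_true, 2 * c1$I_donor_true)
  expect_equal(c2$I_acceptor_true, c1$I_acceptor_true)
})

test_that("noiseless rendering conserves the expected integrated counts", {
  set.seed(9)
  cell <- render_cell(cell_truth(e_true = 0.1), noise = FALSE)
  for (ch in c("donor", "acceptor", "fret")) {
    col <- paste0("I_", ch, "_true")
    expected <- sum(cell$clusters[[col]])
    expect_equal(sum(cell$stacks[[ch]]$voxels), expected,
                 tolerance = 0.02, label = ch)
  }
})

test_that("offset-only cells quantify to zero on average", {
  set.seed(31)
  vals <- replicate(60, {
    cell <- render_cell(cell_truth(has_donor = FALSE, has_acceptor = FALSE))
    quantify_cell(cell$stacks, cell$clicks$x[1], cell$clicks$y[1],
                  phase = "metaphase")$I_donor
  })
  # the peak/placement search selects upward background noise, so pure-noise
  # photometry has a small positive bias; bound it by ~2 sd of the 6x6
  # background sum (sqrt(36 * offset) = 60 counts), far below cluster signals
  expect_lt(abs(mean(vals)), 120)
})

test_that("datasets are pure functions of their seed and truth tables round-trip", {
  d1 <- generate_calibration_dataset(e_true = c(a = 0.1), n_cells_fret = 2,
                                     n_cells_controls = 2, seed = 77)
  d2 <- generate_calibration_dataset(e_true = c(a = 0.1), n_cells_fret = 2,
                                     n_cells_controls = 2, seed = 77)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$cells[[1]]$donor$voxels, d2$cells[[1]]$donor$voxels)

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(d1$truth, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(d1$truth), tolerance = 1e-12)
})

test_that("sensitized emission correlates with acceptor signal under variable maturation", {
  # qualitative reproduction of the acceptor-limited FRET signature
  set.seed(12)
  tr <- cell_truth(e_true = 0.2, maturation_fraction = 0.45)
  ci <- channel_intensities(tr, n_clusters = 300)
  co <- spectral_coefficients(tr$alpha, tr$beta)
  q <- add_fret_quantification(
    dplyr::rename(ci, I_donor = I_donor_true, I_acceptor = I_acceptor_true,
                  I_fret = I_fret_true), co)
  expect_gt(cor(q$sensitized_emission, q$I_acceptor), 0.1)
})

test_that("apparent efficiency scales with maturation on the implied line", {
  mk <- function(m) {
    tr <- cell_truth(e_true = 0.2, maturation_fraction = m)
    ci <- channel_intensities(tr, noiseless = TRUE)
    ref <- channel_intensities(cell_truth(e_true = 0), noiseless = TRUE)
    efficiency_from_donor_quenching(ci$I_donor_true, ref$I_donor_true)$efficiency
  }
  e_full <- mk(1); e_low <- mk(0.3)
  expect_equal(e_low / e_full, 0.3, tolerance = 0.02)
})
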