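test_that("focus search finds the brightest voxel with deterministic tie-breaks", {
  vox <- array(0, dim = c(16, 16, 8))
  vox[6, 6, 4] <- 10 # [y, x, z] = (x = 6, y = 6, z = 4)
  st <- channel_stack(vox)
  fp <- find_focus_plane(st, 7, 7, search_radius_px = 3)
  expect_equal(fp$z, 4L)
  expect_equal(fp$x, 6L)
  expect_equal(fp$y, 6L)
  expect_false(fp$no_signal)

  # equal maxima on two planes: lowest z wins
  vox[6, 6, 7] <- 10
  fp2 <- find_focus_plane(channel_stack(vox), 6, 6, 3)
  expect_equal(fp2$z, 4L)

  # all-zero neighborhood -> flagged, not an error
  fp3 <- find_focus_plane(channel_stack(array(0, dim = c(16, 16, 3))), 8, 8)
  expect_true(fp3$no_signal)

  expect_error(find_focus_plane(st, 40, 8), class = "fretcal_input_error")
})

test_that("focus search respects the lateral radius and a 3-D Gaussian's z argmax", {
  # spot centered between planes 4 and 5, closer to 4: z-profile argmax = 4
  st <- gauss_stack(20, 20, 9, x0 = 10.3, y0 = 9.8, z0 = 4.4,
                    sxy = 1.0, sz = 1.5, mass = 1e5)
  fp <- find_focus_plane(st, 10, 10, 4)
  expect_equal(fp$z, 4L)

  # a far brighter voxel outside the search radius must be ignored
  vox <- st$voxels
  vox[2, 2, 1] <- max(vox) * 10
  fp2 <- find_focus_plane(channel_stack(vox), 10, 10, 4)
  expect_equal(fp2$z, 4L)
  expect_lt(abs(fp2$x - 10), 2)
})

test_that("metaphase box photometry: flat field, single pixel, boundary error", {
  flat <- matrix(7.5, 20, 20)
  m <- measure_metaphase_cluster(flat, 10, 10)
  expect_identical(m$intensity, 0)

  img <- matrix(3, 20, 20)
  img[11, 10] <- 3 + 250 # single pixel of extra value v at (x = 10, y = 11)
  m2 <- measure_metaphase_cluster(img, 10, 11)
  expect_equal(m2$intensity, 250)
  expect_equal(m2$roi$mask_pixel_count, 36L)

  # a 7-row image cannot host the concentric 8x8 background box anywhere
  expect_error(measure_metaphase_cluster(matrix(3, 7, 20), 10, 4),
               class = "fretcal_boundary_error")
})

test_that("metaphase box recovers the numerically integrated Gaussian mass", {
  # oracle: direct numerical sum of the generating function over the chosen box
  A <- 320; s <- 1.2; b <- 12; x0 <- 15.4; y0 <- 14.8
  img <- gauss_plane(30, 30, x0, y0, s, s, A, b)
  m <- measure_metaphase_cluster(img, 15, 15)
  ox <- m$roi$box_origin[["x"]]; oy <- m$roi$box_origin[["y"]]
  box_mass <- sum(gauss_plane(30, 30, x0, y0, s, s, A, 0)[oy:(oy + 5), ox:(ox + 5)])
  # rim median still carries a trace of the spot tail; tolerance covers it
  expect_equal(m$intensity, box_mass, tolerance = 0.02)
})

test_that("metaphase box method keeps >= 90% of spot mass at realistic widths", {
  total_frac <- vapply(c(0.5, 0.8, 1.1, 1.25), function(s) {
    img <- gauss_plane(30, 30, 15.6, 15.2, s, s, A = 400, b = 20)
    m <- measure_metaphase_cluster(img, 16, 15)
    m$intensity / (2 * pi * 400 * s^2)
  }, numeric(1))
  expect_true(all(total_frac >= 0.90))
  expect_true(all(total_frac <= 1.005))
  # at sigma = 1.5 the 6x6 box truncation plus rim-median contamination
  # intrinsically costs ~15%; characterize rather than pretend otherwise
  img <- gauss_plane(30, 30, 15.6, 15.2, 1.5, 1.5, A = 400, b = 20)
  m <- measure_metaphase_cluster(img, 16, 15)
  expect_gt(m$intensity / (2 * pi * 400 * 1.5^2), 0.80)
})

test_that("anaphase Gaussian photometry matches the analytic ellipse mass", {
  A <- 500; sx <- 2.0; sy <- 1.6; b <- 30
  img <- gauss_plane(41, 41, 21.3, 20.7, sx, sy, A, b)
  m <- measure_anaphase_cluster(img, 21, 21, fit_window_px = 21)
  analytic <- 2 * pi * A * sx * sy * (1 - exp(-2.5^2 / 2))
  expect_equal(m$intensity, analytic, tolerance = 0.005)
  expect_equal(m$roi$sigma[["x"]], sx, tolerance = 0.01)

  # offset invariance: raising the background changes nothing
  m2 <- measure_anaphase_cluster(img + 50, 21, 21, fit_window_px = 21)
  expect_equal(m2$intensity, m$intensity, tolerance = 1e-6)

  # flat image -> classed fit failure
  expect_error(measure_anaphase_cluster(matrix(40, 41, 41), 21, 21),
               class = "fretcal_fit_failed")
})

test_that("both ROI methods are translation-equivariant and exactly linear", {
  base <- function(x0, y0, scale = 1) {
    gauss_plane(36, 36, x0, y0, 1.1, 1.1, A = 300 * scale, b = 15 * scale)
  }
  m0 <- measure_metaphase_cluster(base(15.3, 16.6), 15, 17)
  m_shift <- measure_metaphase_cluster(base(20.3, 13.6), 20, 14)
  expect_equal(m_shift$intensity, m0$intensity, tolerance = 1e-3)

  a0 <- measure_anaphase_cluster(base(15.3, 16.6), 15, 17)
  a_shift <- measure_anaphase_cluster(base(20.3, 13.6), 20, 14)
  expect_equal(a_shift$intensity, a0$intensity, tolerance = 1e-3)

  # linearity: scaling the image scales the corrected intensity exactly
  m2 <- measure_metaphase_cluster(base(15.3, 16.6, scale = 3), 15, 17)
  expect_equal(m2$intensity, 3 * m0$intensity, tolerance = 1e-9)
})

test_that("quantify_cell shares one ROI across channels and validates inputs", {
  st <- gauss_stack(24, 24, 7, 12.4, 11.7, 4.2, sxy = 0.9, sz = 1.5,
                    mass = 5e4, b = 50)
  stacks <- list(
    donor = st,
    acceptor = channel_stack(st$voxels, channel = "acceptor"),
    fret = channel_stack(st$voxels, channel = "fret")
  )
  q <- quantify_cell(stacks, 12, 12, phase = "metaphase", cell_id = "c1")
  expect_equal(q$I_donor, q$I_acceptor)
  expect_equal(q$I_donor, q$I_fret)
  roi <- jsonlite::fromJSON(q$roi_params)
  expect_identical(roi$method, "metaphase_box")
  expect_identical(roi$focus_z, q$focus_z)

  # zero acceptor channel: acceptor intensity 0, others unchanged
  stacks$acceptor <- channel_stack(array(0, dim(st$voxels)), channel = "acceptor")
  q2 <- quantify_cell(stacks, 12, 12, phase = "metaphase")
  expect_equal(q2$I_acceptor, 0)
  expect_equal(q2$I_donor, q$I_donor)

  # shape mismatch across channels
  stacks$acceptor <- channel_stack(array(0, dim = c(24, 24, 5)),
                                   channel = "acceptor")
  expect_error(quantify_cell(stacks, 12, 12, phase = "metaphase"),
               class = "fretcal_input_error")
})

test_that("a failed anaphase fit is flagged as zero signal, not an error", {
  flat <- channel_stack(array(80, dim = c(24, 24, 5)))
  stacks <- list(donor = flat,
                 acceptor = channel_stack(flat$voxels, channel = "acceptor"),
                 fret = channel_stack(flat$voxels, channel = "fret"))
  q <- quantify_cell(stacks, 12, 12, phase = "anaphase")
  expect_false(q$fit_ok)
  expect_equal(q$I_donor, 0)
})
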