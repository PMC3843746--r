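edges_default <- seq(0, 12.5, length.out = 257)

test_that("decay model: delta-IRF identity, linearity, exact exponential ratio", {
  irf_delta <- gaussian_irf(edges_default, edges_default[1], 0)
  y <- decay_model(1000, 2.24, irf_delta)
  # delta response: model is the bin-integrated exponential itself
  dt <- diff(edges_default)[1]
  lo <- pmax(0, (seq_len(256) - 1.5) * dt); hi <- pmax(0, (seq_len(256) - 0.5) * dt)
  expect_equal(y, 1000 * (2.24 / dt) * (exp(-lo / 2.24) - exp(-hi / 2.24)))

  # ratio across exactly one lifetime is 1/e (bins past the rise)
  k <- round(2.24 / dt)
  expect_equal(y[200] / y[200 - k], exp(-k * dt / 2.24), tolerance = 1e-12)

  # linearity in amplitudes
  irf <- gaussian_irf(edges_default, 1, 0.1)
  y1 <- decay_model(c(500, 200), c(2.28, 0.61), irf)
  y2 <- decay_model(c(1000, 400), c(2.28, 0.61), irf)
  expect_equal(y2, 2 * y1)
  # area conservation up to window truncation (< 1% here)
  expect_equal(sum(y1),
               sum(decay_model(500, 2.28, irf)) + sum(decay_model(200, 0.61, irf)))
})

test_that("fitting the model's own output returns the generating parameters", {
  irf <- gaussian_irf(edges_default, 1, 0.1)
  m <- decay_model(c(2e6, 1e6), c(2.28, 0.61), irf)
  h <- decay_histogram(edges_default, round(m))
  f <- fit_decay(h, irf, 2, method = "neyman")
  expect_equal(f$components$lifetime, c(2.28, 0.61), tolerance = 1e-6)
  expect_equal(f$components$amplitude, c(2e6, 1e6), tolerance = 1e-6)
  # chi^2 floor set by rounding model counts to integers, not by the fit
  expect_lt(f$reduced_chi_squared, 1e-3)
})

test_that("biexponential fits recover Table-1-scale parameters from sampled photons", {
  gd <- generate_decay(c(532.1, 239.4), c(2.28, 0.61), n_photons = 1e5, seed = 11)
  f <- fit_decay(gd$histogram, gd$irf, 2)
  expect_equal(f$components$lifetime[1], 2.28, tolerance = 0.05)
  expect_equal(f$components$lifetime[2], 0.61, tolerance = 0.10)
  expect_equal(fraction_with_acceptor(f), 239.4 / (532.1 + 239.4),
               tolerance = 0.10)
  # ordering convention: reported tau1 >= tau2
  expect_gte(f$components$lifetime[1], f$components$lifetime[2])

  gd1 <- generate_decay(745, 2.24, n_photons = 1e5, seed = 12)
  f1 <- fit_decay(gd1$histogram, gd1$irf, 1)
  expect_equal(f1$components$lifetime, 2.24, tolerance = 0.05)
})

test_that("derived quantities follow the amplitude-fraction and lifetime formulas", {
  mk_fit <- function(a1, a2, t1, t2) {
    structure(list(components = tibble::tibble(amplitude = c(a1, a2),
                                               lifetime = c(t1, t2)),
                   n_components = 2L), class = "flim_fit")
  }
  expect_equal(fraction_with_acceptor(mk_fit(500, 0, 2.3, 0.6)), 0)
  expect_equal(fraction_with_acceptor(mk_fit(532.1, 239.4, 2.28, 0.61)),
               0.3103, tolerance = 1e-4)
  expect_equal(fraction_with_acceptor(mk_fit(828.4, 242, 2.24, 0.66)),
               0.2261, tolerance = 1e-4)

  expect_equal(efficiency_from_lifetimes(2.0, 2.0), 0)
  expect_equal(efficiency_from_lifetimes(2.28, 0.61), 1 - 0.61 / 2.28)
  expect_equal(efficiency_from_lifetimes(2.24, 0.66), 1 - 0.66 / 2.24)
  expect_error(efficiency_from_lifetimes(1, 2), class = "fretcal_domain_error")

  one_comp <- structure(list(n_components = 1L), class = "flim_fit")
  expect_error(fraction_with_acceptor(one_comp), class = "fretcal_input_error")
})

test_that("decay generator: mean arrival time, determinism, photon floor", {
  gd <- generate_decay(1, 2.24, n_photons = 1e6, irf_width_ns = 0.05,
                       t_max_ns = 30, n_bins = 600, seed = 21)
  tc <- (gd$histogram$bin_edges[-1] + head(gd$histogram$bin_edges, -1)) / 2
  emp_mean <- sum(tc * gd$histogram$counts) / sum(gd$histogram$counts)
  expect_equal(emp_mean - 1, 2.24, tolerance = 0.01)

  g1 <- generate_decay(c(2, 1), c(2.3, 0.7), n_photons = 5000, seed = 33)
  g2 <- generate_decay(c(2, 1), c(2.3, 0.7), n_photons = 5000, seed = 33)
  expect_identical(g1$histogram$counts, g2$histogram$counts)

  few <- generate_decay(1, 2, n_photons = 200, seed = 1)
  expect_error(fit_decay(few$histogram, few$irf, 1),
               class = "fretcal_input_error")
})

test_that("the F-test helper prefers two components only when they exist", {
  gd <- generate_decay(c(532.1, 239.4), c(2.28, 0.61), n_photons = 1e5, seed = 44)
  f1 <- fit_decay(gd$histogram, gd$irf, 1)
  f2 <- fit_decay(gd$histogram, gd$irf, 2)
  cmp <- compare_decay_fits(f1, f2)
  expect_lt(cmp$p_value, 1e-6)

  mono <- generate_decay(700, 2.24, n_photons = 1e5, seed = 45)
  m1 <- fit_decay(mono$histogram, mono$irf, 1)
  m2 <- fit_decay(mono$histogram, mono$irf, 2)
  expect_lt(compare_decay_fits(m1, m2)$f_statistic, cmp$f_statistic)
})
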