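test_that("ring chord distances match the closed form in both geometry modes", {
  d <- ring_distances(13, diameter_nm = 25)
  expect_equal(d[1, 2], 25 * sin(pi / 13))
  expect_equal(d[1, 2], 5.98, tolerance = 0.002)
  expect_equal(d[1, 3], 11.62, tolerance = 0.001)
  expect_true(isSymmetric(d))
  expect_equal(diag(d), rep(0, 13))
  # second neighbors sit outside the default 10 nm FRET radius
  expect_gt(d[1, 3], 10)

  ds <- ring_distances(13, adjacent_spacing_nm = 6.15)
  expect_equal(ds[1, 2], 6.15)

  expect_equal(ring_distances(2, 20)[1, 2], 20)
  expect_error(ring_distances(1), class = "fretcal_input_error")

  # cross-check chords against explicit planar coordinates
  xy <- ring_xy(13, 25)
  expect_equal(d, unname(as.matrix(stats::dist(xy))), tolerance = 1e-12)
})

test_that("labeling schemes and maturation behave as specified", {
  cfg_all <- ring_config(p_donor = 1, replicates = 5, seed = 1)
  expect_true(all(assign_labels(cfg_all)))
  cfg_none <- ring_config(n_donor = 0, replicates = 5, seed = 1)
  expect_false(any(assign_labels(cfg_none)))

  cfg6 <- ring_config(n_donor = 6, replicates = 200, seed = 2)
  labs <- assign_labels(cfg6)
  expect_true(all(rowSums(labs) == 6))
  expect_error(ring_config(n_donor = 14), class = "fretcal_input_error")

  # full maturation: everything fluoresces
  expect_true(all(apply_maturation(labs, cfg6)))

  # acceptor maturation 0.25: fluorescent-acceptor count is Binomial(10, 0.25)
  cfg <- ring_config(n_donor = 3, maturation_acceptor = 0.25,
                     replicates = 10000, seed = 3)
  with_seed <- function(s, code) { set.seed(s); code }
  labs <- with_seed(11, assign_labels(cfg))
  fl <- with_seed(12, apply_maturation(labs, cfg))
  n_acc_fluor <- rowSums(fl & !labs)
  se <- sd(n_acc_fluor) / sqrt(length(n_acc_fluor))
  expect_lt(abs(mean(n_acc_fluor) - 10 * 0.25), 3 * se)
  # dead acceptors can never fluoresce
  cfg0 <- ring_config(maturation_acceptor = 0, replicates = 50, seed = 4)
  labs0 <- assign_labels(cfg0)
  expect_false(any(apply_maturation(labs0, cfg0) & !labs0))
})

test_that("pair counting agrees with a brute-force coordinate oracle in every mode", {
  d <- ring_distances(13, 25)
  set.seed(31)
  for (i in 1:60) {
    donors <- runif(13) < runif(1, 0.15, 0.85)
    fluor <- runif(13) < runif(1, 0.3, 1)
    radius <- sample(c(7, 10, 13, 26), 1)
    for (mode in c("pair_count", "donor_count", "matching")) {
      expect_identical(
        count_fret_pairs(donors, fluor, d, radius, mode),
        as.integer(oracle_counts(donors, fluor, 13, 25, radius, mode)),
        info = sprintf("mode %s radius %s rep %d", mode, radius, i))
    }
  }
})

test_that("structural count inequalities hold: matching <= donor_count <= pair_count", {
  d <- ring_distances(13, 25)
  set.seed(77)
  for (i in 1:40) {
    donors <- runif(13) < 0.5
    fluor <- runif(13) < 0.6
    pc <- count_fret_pairs(donors, fluor, d, 10, "pair_count")
    dc <- count_fret_pairs(donors, fluor, d, 10, "donor_count")
    mm <- count_fret_pairs(donors, fluor, d, 10, "matching")
    expect_lte(mm, dc)
    expect_lte(dc, pc)
    expect_lte(mm, min(sum(donors & fluor), sum(!donors & fluor)))
  }
  # all donors -> zero in every mode
  for (mode in c("pair_count", "donor_count", "matching")) {
    expect_identical(count_fret_pairs(rep(TRUE, 13), rep(TRUE, 13), d, 10, mode), 0L)
  }
})

test_that("simulated distributions are seeded-reproducible and well normalized", {
  cfg <- ring_config(replicates = 500, seed = 99)
  r1 <- simulate_ring(cfg)
  r2 <- simulate_ring(cfg)
  expect_identical(r1$counts, r2$counts)
  expect_equal(sum(r1$histogram$probability), 1, tolerance = 1e-9)
  expect_equal(sum(r1$histogram$pairs * r1$histogram$probability), r1$mean)
  expect_true(all(r1$counts <= 13^2 / 4))

  one <- simulate_ring(ring_config(replicates = 1, seed = 5))
  expect_identical(one$counts, simulate_ring(ring_config(replicates = 1, seed = 5))$counts)
})

test_that("unbiased Bernoulli labeling yields 13/2 expected pairs", {
  # analytic: 13 adjacent pairs x P(mixed) = 13/2 at full maturation
  res <- simulate_ring(ring_config(replicates = 10000, seed = 17))
  expect_lt(abs(res$mean - 6.5), 3 * res$se)
  expect_true(res$mean >= 6 && res$mean <= 7)
})

test_that("fixed-count simulation matches exhaustive enumeration (spot checks)", {
  for (g in c(2, 6, 10)) {
    for (mode in c("pair_count", "matching")) {
      sim <- simulate_ring(ring_config(n_donor = g, counting_mode = mode,
                                       replicates = 4000, seed = 40 + g))
      exact <- enumerate_ring_mean(g, 13, 25, 10, mode)
      expect_lt(abs(sim$mean - exact), 3 * max(sim$se, 1e-12),
                label = sprintf("g=%d mode=%s sim=%.3f exact=%.3f", g, mode,
                                sim$mean, exact))
      if (mode == "pair_count") expect_equal(exact, g * (13 - g) / 6)
    }
  }
})

test_that("donor/acceptor exchange symmetry holds for pair counts", {
  means <- vapply(c(3, 10), function(g) {
    simulate_ring(ring_config(n_donor = g, replicates = 6000, seed = 55))$mean
  }, numeric(1))
  # exact means are equal (g vs n - g); compare within Monte Carlo error
  expect_lt(abs(means[1] - means[2]), 0.12)
})

test_that("abundance scan finds the balanced optimum and zero endpoints", {
  sc <- scan_donor_abundance(ring_config(replicates = 6000, seed = 8))
  expect_equal(sc$scan$mean_pairs[sc$scan$n_donor == 0], 0)
  expect_equal(sc$scan$mean_pairs[sc$scan$n_donor == 13], 0)
  expect_setequal(sc$maximizing_set, c(6, 7))
  expect_equal(sc$optimum, 6.5)
  # means track g(13 - g)/6 within Monte Carlo error
  expect_equal(sc$scan$mean_pairs,
               sc$scan$n_donor * (13 - sc$scan$n_donor) / 6,
               tolerance = 0.02)
})

test_that("bias correction factor is the balanced-to-biased mean ratio", {
  sc <- scan_donor_abundance(ring_config(replicates = 8000, seed = 13))
  expect_equal(bias_correction_factor(sc, 6), 1, tolerance = 0.01)
  # analytic expectation ratio: (6*7/6) / (3*10/6) = 1.4
  expect_equal(bias_correction_factor(sc, 3), 1.4, tolerance = 0.02)
  # non-decreasing with bias away from balance
  f <- vapply(6:12, function(g) bias_correction_factor(sc, g), numeric(1))
  expect_true(all(diff(f) > -0.01))
  expect_error(bias_correction_factor(sc, 13), class = "fretcal_domain_error")
})
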