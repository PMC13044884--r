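# ISTD correction, response-factor averaging, the relative-deviation
# outlier filter, and the log transform.

test_that("istd_correct divides analyte area by internal-standard area", {
  expect_equal(istd_correct(100, 100), 1)
  expect_equal(istd_correct(0, 5), 0)
  expect_equal(istd_correct(0.2, 0.1), 2)
  expect_error(istd_correct(1, 0, sample_id = "s9"), "s9")
  expect_error(istd_correct(-1, 1), "negative")
})

test_that("compute_alpha averages per-measurement response factors", {
  m <- tibble::tibble(
    sample_id = c("a", "b"), molecule_id = "m",
    concentration_mg_per_kg = c(0.01, 0.1),
    area = c(0.02, 0.2), istd_area = 1)
  rec <- compute_alpha(m)
  expect_equal(unname(rec$alphas[[1]]), c(2, 2))
  expect_equal(rec$mean_alpha, 2)

  one <- compute_alpha(measurements_from_alpha(3))
  expect_equal(one$mean_alpha, 3)
})

test_that("compute_alpha matches a brute-force mean on random rows", {
  set.seed(42)
  m <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:100),
    molecule_id = sample(c("m1", "m2", "m3"), 100, replace = TRUE),
    concentration_mg_per_kg = runif(100, 0.001, 0.1),
    area = runif(100, 10, 1000),
    istd_area = runif(100, 50, 150))
  rec <- compute_alpha(m)
  for (mol in rec$molecule_id) {
    rows <- m[m$molecule_id == mol, ]
    oracle <- mean((rows$area / rows$istd_area) / rows$concentration_mg_per_kg)
    expect_equal(rec$mean_alpha[rec$molecule_id == mol], oracle)
  }
})

test_that("exclusions and zero-area rows land in the rejects list", {
  m <- measurements_from_alpha(c(1, 2, 0), molecule_id = "m1")
  m2 <- measurements_from_alpha(c(5, 5), molecule_id = "m2")
  m2$sample_id <- c("x1", "x2")
  rec <- compute_alpha(dplyr::bind_rows(m, m2), exclusions = "m2")
  rejects <- attr(rec, "rejects")
  expect_setequal(rejects$reason[rejects$molecule_id == "m2"],
                  "excluded")
  expect_true("nonpositive_alpha" %in% rejects$reason)
  expect_equal(rec$molecule_id, "m1")
  expect_equal(rec$n_kept, 2L)

  # a molecule whose every row is excluded is reported, not dropped silently
  rec2 <- compute_alpha(m2, exclusions = c("x1", "x2"))
  r2 <- attr(rec2, "rejects")
  expect_true("no_usable_measurements" %in% r2$reason)
})

test_that("outlier filter applies the +-0.5*mean rule in a single pass", {
  # mean 12, max deviation 4 <= 6: nothing flagged
  rec <- flag_outliers(compute_alpha(measurements_from_alpha(c(10, 10, 16))))
  expect_equal(rec$n_flagged, 0L)
  expect_equal(rec$mean_alpha, 12)

  # mean 14, deviation of 22 is 8 > 7: flagged, mean recomputed to 10
  rec <- flag_outliers(compute_alpha(measurements_from_alpha(c(10, 10, 22))))
  expect_equal(rec$n_flagged, 1L)
  expect_equal(rec$mean_alpha, 10)
  expect_equal(rec$mean_alpha_all, 14)
  expect_equal(rec$flagged[[1]], "s3")

  # zero deviation: nothing flagged
  rec <- flag_outliers(compute_alpha(measurements_from_alpha(c(5, 5, 5))))
  expect_equal(rec$n_flagged, 0L)

  # boundary is strict: deviation exactly 0.5*mean stays
  rec <- flag_outliers(compute_alpha(measurements_from_alpha(c(2, 2, 2, 4))))
  # mean 2.5, threshold 1.25, deviation of 4 is 1.5 > 1.25 -> flagged
  expect_equal(rec$n_flagged, 1L)
  rec <- flag_outliers(compute_alpha(measurements_from_alpha(c(1, 3))))
  # mean 2, deviations exactly 1 = 0.5*2: kept
  expect_equal(rec$n_flagged, 0L)
})

test_that("filter keeps everything (with a warning) if all would be flagged", {
  rec <- compute_alpha(measurements_from_alpha(c(1, 100)))
  expect_warning(out <- flag_outliers(rec), "keeping all")
  expect_equal(out$n_flagged, 0L)
  expect_equal(out$mean_alpha, 50.5)
})

test_that("filtering an already-filtered record flags nothing new", {
  rec <- flag_outliers(compute_alpha(measurements_from_alpha(c(10, 10, 22))))
  again <- flag_outliers(rec)
  expect_equal(again$n_flagged, 0L)
  expect_equal(again$mean_alpha, rec$mean_alpha)
})

test_that("compute_beta is the natural log of the mean response factor", {
  rec <- compute_alpha(measurements_from_alpha(1))
  expect_equal(compute_beta(flag_outliers(rec))$beta, 0)
  rec <- compute_alpha(measurements_from_alpha(exp(1)))
  expect_equal(compute_beta(flag_outliers(rec))$beta, 1)
  # strictly increasing in mean_alpha
  b <- vapply(c(0.5, 1, 2, 10), function(a)
    compute_beta(flag_outliers(compute_alpha(measurements_from_alpha(a))))$beta,
    0)
  expect_true(all(diff(b) > 0))
})

test_that("preprocessing output is invariant to row order", {
  spec <- synthetic_spec(n_molecules = 6, outlier_fraction = 0.05, seed = 21)
  m <- simulate_study(spec)$measurements
  b1 <- preprocess_measurements(m)
  b2 <- preprocess_measurements(m[rev(seq_len(nrow(m))), ])
  b2 <- b2[match(b1$molecule_id, b2$molecule_id), ]
  expect_equal(b1$beta, b2$beta)
  expect_equal(b1$n_flagged, b2$n_flagged)
})

test_that("zero-noise synthetic data round-trips beta to machine precision", {
  spec <- synthetic_spec(n_molecules = 12, signal_noise_cv = 0,
                         beta_noise_sd = 0, outlier_fraction = 0, seed = 13)
  study <- simulate_study(spec)
  beta <- preprocess_measurements(study$measurements)
  truth <- study$ground_truth
  beta <- beta[match(truth$molecule_id, beta$molecule_id), ]
  expect_lt(max(abs(beta$beta - truth$beta_true)), 1e-12)
})

test_that("injected outliers are recovered exactly at zero signal noise", {
  spec <- synthetic_spec(n_molecules = 40, signal_noise_cv = 0,
                         beta_noise_sd = 0.1, outlier_fraction = 0.05,
                         outlier_offset = 0.8, seed = 17)
  study <- simulate_study(spec)
  beta <- preprocess_measurements(study$measurements)
  flagged <- attr(beta, "flagged")
  expect_setequal(flagged$sample_id, study$outliers$sample_id)
  truth <- study$ground_truth
  beta <- beta[match(truth$molecule_id, beta$molecule_id), ]
  expect_lt(max(abs(beta$beta - truth$beta_true)), 1e-12)
})
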