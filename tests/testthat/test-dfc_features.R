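test_that("analytic phase tracks the true phase of a narrowband oscillation", {
  tr <- 2
  f <- 0.05
  t <- (0:999) * tr
  ph <- analytic_phase(cos(2 * pi * f * t))
  interior <- 100:900
  increments <- diff(ph)[interior]
  increments <- wrap_phase(increments)
  expect_lt(max(abs(increments - 2 * pi * f * tr)) / (2 * pi * f * tr), 0.01)
  # quadrature: sin lags cos by pi/2
  ph_sin <- analytic_phase(sin(2 * pi * f * t))
  dp <- wrap_phase(ph_sin[interior] - ph[interior])
  expect_lt(max(abs(dp + pi / 2)), 0.02)
})

test_that("degenerate series are rejected by the phase estimator", {
  expect_error(analytic_phase(rep(1, 100)), "constant")
  expect_error(analytic_phase(rep(0, 100)), "constant")
  expect_error(analytic_phase(rnorm(5)), "too short")
  expect_error(analytic_phase(c(rnorm(20), NA)), "non-finite")
})

test_that("wrap_phase maps onto the half-open interval (-pi, pi]", {
  expect_equal(wrap_phase(0), 0)
  expect_equal(wrap_phase(3 * pi / 2), -pi / 2)
  expect_equal(wrap_phase(-pi), pi)
  expect_equal(wrap_phase(pi), pi)
  expect_equal(wrap_phase(7 * pi / 3), pi / 3, tolerance = 1e-12)
  x <- seq(-20, 20, length.out = 4001)
  w <- wrap_phase(x)
  expect_true(all(w > -pi & w <= pi))
  expect_equal(sin(w), sin(x), tolerance = 1e-9)
  expect_equal(cos(w), cos(x), tolerance = 1e-9)
  expect_error(wrap_phase(c(1, Inf)), "finite")
})

test_that("inter-network variability is zero for identical series and tiny for constant offsets", {
  set.seed(31)
  for (r in 1:20) {
    x <- bandpass(rnorm(240), 2)
    expect_lt(inter_icn_variability(x, x), 1e-12)
  }
  t <- (0:499) * 2
  x <- cos(2 * pi * 0.05 * t)
  y <- cos(2 * pi * 0.05 * t - 0.7)
  expect_lt(inter_icn_variability(x, y), 1e-3)
})

test_that("the variance estimator reaches the uniform limit pi^2/3", {
  set.seed(17)
  dphi <- runif(100000, -pi, pi)
  v <- phase_difference_variance(dphi, trim = 0)
  expect_lt(abs(v - pi^2 / 3) / (pi^2 / 3), 0.02)
})

test_that("pipeline variance equals the brute-force oracle", {
  set.seed(55)
  for (r in 1:100) {
    dphi <- runif(sample(50:200, 1), -4 * pi, 4 * pi)
    expect_lt(abs(phase_difference_variance(dphi) -
                    brute_force_phase_variance(dphi)), 1e-10)
  }
})

test_that("estimated VAR increases with planted wrapped-normal dispersion", {
  sig2 <- c(0.01, 0.1, 0.5)
  set.seed(99)
  for (rep in 1:50) {
    ests <- vapply(sig2, function(s2)
      phase_difference_variance(rnorm(500, 0, sqrt(s2))), numeric(1))
    expect_true(all(diff(ests) > 0))
  }
})

test_that("VAR and PS are symmetric and amplitude-invariant; FC is symmetric", {
  set.seed(12)
  x <- bandpass(rnorm(240), 2)
  y <- bandpass(rnorm(240), 2)
  expect_identical(inter_icn_variability(x, y), inter_icn_variability(y, x))
  expect_identical(phase_synchrony(x, y), phase_synchrony(y, x))
  expect_identical(functional_connectivity(x, y), functional_connectivity(y, x))
  for (c_amp in c(0.1, 3, 250)) {
    expect_lt(abs(inter_icn_variability(c_amp * x, y) -
                    inter_icn_variability(x, y)), 1e-10)
    expect_lt(abs(phase_synchrony(x, c_amp * y) - phase_synchrony(x, y)), 1e-10)
  }
})

test_that("functional connectivity matches its defining identities", {
  set.seed(2)
  x <- rnorm(100)
  expect_equal(functional_connectivity(x, x), 1)
  expect_equal(functional_connectivity(x, -x), -1)
  expect_error(functional_connectivity(x, rep(2, 100)), "constant")
  expect_error(functional_connectivity(x, rnorm(50)), "equal length")
  # independent noise: |r| small in >= 95% of seeds
  hits <- vapply(1:40, function(s) {
    set.seed(400 + s)
    abs(functional_connectivity(rnorm(10000), rnorm(10000))) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("phase synchrony is 1 under identity or constant offset and ~0 for independent phases", {
  t <- (0:499) * 2
  x <- cos(2 * pi * 0.05 * t)
  expect_equal(phase_synchrony(x, x), 1, tolerance = 1e-12)
  y <- cos(2 * pi * 0.05 * t - 1.1)
  expect_gt(phase_synchrony(x, y), 0.999)
  # uniform independent phase differences: PLV ~ T^(-1/2)
  hits <- vapply(1:40, function(s) {
    set.seed(700 + s)
    dphi <- runif(10000, -pi, pi)
    Mod(mean(exp(1i * dphi))) < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("pairwise feature vectors follow the canonical upper-triangle order", {
  cfg <- small_config(n = 1)
  tc <- simulate_timecourses(cfg, "control", seed = 3)
  v <- pairwise_features(tc, "VAR")
  expect_length(v, 45)
  expect_equal(names(v)[1:3], c("MVN-OVN", "MVN-LVN", "MVN-DMN"))
  expect_equal(names(v)[45], "RFPN-LFPN")
  expect_true(all(v >= 0))
  # N = 3 -> 3 pairs
  expect_length(pairwise_features(tc[, 1:3], "FC"), 3)
  fc <- pairwise_features(tc, "FC")
  expect_true(all(fc >= -1 & fc <= 1))
  ps <- pairwise_features(tc, "PS")
  expect_true(all(ps >= 0 & ps <= 1))
  # failing pair is named
  bad <- tc
  bad[, 2] <- 0
  expect_error(pairwise_features(bad, "VAR"), "MVN, OVN")
})

test_that("VAR on identical columns is all zeros", {
  x <- bandpass(rnorm(240), 2)
  tc <- cbind(a = x, b = x, c = x)
  expect_true(all(pairwise_features(tc, "VAR") < 1e-12))
})

test_that("feature assembly matches the diagnostic-model term order and ablations", {
  cfg <- small_config(n = 1, seed = 8)
  co <- simulate_cohort(cfg)
  pairs <- pairwise_features(co$timecourses[[1]], "VAR")
  rec <- co$phenotypes[1, ]
  full <- assemble_feature_vector(pairs, rec)
  expect_length(full, 51)
  expect_equal(names(full)[46:51], c("viq", "piq", "fiq", "sex", "age", "mean_fd"))
  expect_length(assemble_feature_vector(pairs, rec, include_iq = FALSE), 48)
  expect_length(assemble_feature_vector(pairs, rec, include_motion = FALSE), 50)
  expect_true(full["sex"] %in% c(0, 1))
  rec2 <- rec
  rec2$fiq <- NULL
  expect_error(assemble_feature_vector(pairs, rec2), "fiq")
})

test_that("cohort feature matrices line up with phenotype labels", {
  cfg <- small_config(n = 4, seed = 10)
  co <- simulate_cohort(cfg)
  f <- cohort_features(co, "VAR")
  expect_equal(dim(f$X), c(8, 51))
  expect_equal(f$y, c(rep(1L, 4), rep(0L, 4)))
  expect_equal(rownames(f$X), co$phenotypes$subject_id)
  # raw (unfiltered) variant also runs and differs
  f2 <- cohort_features(co, "VAR", filter_band = FALSE)
  expect_false(isTRUE(all.equal(f$X[, 1], f2$X[, 1])))
})
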