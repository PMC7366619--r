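test_that("r_squared matches hand-computed sums of squares", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  obs <- c(0, 1, 2, 3)
  expect_equal(r_squared(obs, rep(mean(obs), 4)), 0)
  expect_equal(r_squared(obs, c(0.1, 0.9, 2.1, 2.9)), 0.992)
  expect_error(r_squared(c(1, 1, 1), c(1, 1, 1)), "constant")
  expect_error(r_squared(1:3, 1:4), "equal length")
})

test_that("noiseless four-regime curve is recovered exactly", {
  # distinct fourth slope keeps all three change points identifiable
  d <- make_pwl4_curve(slopes = c(20, 150, 500, 800))
  sf <- fit_segmented(d, seed = 1)
  expect_true(sf$converged)
  expect_equal(sf$psi, c(0.20, 0.35, 0.60), tolerance = 1e-6)
  expect_equal(sf$slopes, c(20, 150, 500, 800), tolerance = 1e-6)
  expect_equal(sf$r2, 1, tolerance = 1e-9)
  expect_true(all(sf$psi_se < 1e-6))   # noiseless: SE at machine scale

  # with slope3 == slope4 the third change point is non-identifiable but
  # slopes and fit quality are still exact
  d2 <- make_pwl4_curve(slopes = c(20, 150, 500, 500), strain_max = 0.8)
  sf2 <- suppressWarnings(fit_segmented(d2, seed = 1))
  expect_equal(sf2$slopes, c(20, 150, 500, 500), tolerance = 1e-6)
  expect_equal(sf2$psi[1:2], c(0.20, 0.35), tolerance = 1e-6)
  expect_equal(sf2$r2, 1, tolerance = 1e-9)
})

test_that("straight-line data degenerate to equal slopes with a warning", {
  x <- seq(0, 0.8, length.out = 120)
  d <- data.frame(strain = x, stress = 100 * x)
  expect_warning(sf <- fit_segmented(d, seed = 1), "degenerate")
  expect_equal(sf$slopes, rep(100, 4), tolerance = 1e-8)
  expect_true(sf$degenerate)
})

test_that("segmented SSE never exceeds the single-line SSE (nesting)", {
  for (s in 1:5) {
    d <- make_pwl4_curve(n = 80, noise_rel = 0.05, noise_abs = 0.2,
                         seed = 100 + s)
    sf <- suppressWarnings(fit_segmented(d, seed = s))
    line_sse <- sum(resid(lm(stress ~ strain, data = d))^2)
    expect_lte(sf$sse, line_sse)
  }
})

test_that("iterative fit matches the exhaustive grid oracle on small curves", {
  # deeper battery lives in test-acceptance.R; spot-check here
  for (s in 1:5) {
    d <- make_pwl4_curve(n = 40, noise_rel = 0.02, noise_abs = 0.05,
                         seed = 200 + s)
    sf <- suppressWarnings(fit_segmented(d, seed = s))
    expect_lte(sf$sse, grid_oracle_sse(d$strain, d$stress) * (1 + 1e-6) + 1e-12)
  }
})

test_that("noiseless runs are seed-invariant; noisy averages follow definition", {
  d <- make_pwl4_curve(slopes = c(20, 150, 500, 800))
  fits <- lapply(1:5, function(s) fit_segmented(d, seed = s))
  for (f in fits[-1]) {
    expect_identical(f$psi, fits[[1]]$psi)
    expect_identical(f$slopes, fits[[1]]$slopes)
  }

  # estimate_moduli averages slope 1 -> E1 and slope 3 -> E2 over runs
  spec <- synthetic_spec("bilinear",
                         list(E1 = 20, E2 = 500,
                              heel_start = 0.35, heel_end = 0.35),
                         noise_rel = 0.02, n_replicates = 3,
                         truth_jitter = 0, seed = 42)
  st <- gen_replicate_set(spec)
  me <- suppressWarnings(estimate_moduli(st, n_runs = 4, n_boot = 3,
                                         base_seed = 7))
  expect_equal(me$seeds, 7:10)
  s1 <- vapply(me$runs, function(f) f$slopes[1], numeric(1))
  s3 <- vapply(me$runs, function(f) f$slopes[3], numeric(1))
  expect_equal(me$E1, mean(s1))
  expect_equal(me$E2, mean(s3))
})

test_that("noiseless kink world recovers (20, 500) exactly through the pipeline", {
  spec <- synthetic_spec("bilinear",
                         list(E1 = 20, E2 = 500,
                              heel_start = 0.35, heel_end = 0.35),
                         noise_rel = 0, noise_abs = 0, n_replicates = 3,
                         truth_jitter = 0, seed = 2)
  st <- gen_replicate_set(spec)
  me <- suppressWarnings(estimate_moduli(st, n_runs = 3, n_boot = 3,
                                         base_seed = 1))
  expect_equal(me$E1, 20, tolerance = 1e-9)
  expect_equal(me$E2, 500, tolerance = 1e-9)
  expect_true(all(me$psi_se < 1e-6))
})

test_that("SE(psi) shrinks as the number of points grows", {
  se_at <- function(n) {
    d <- make_pwl4_curve(n = n, noise_rel = 0.02, noise_abs = 0.05,
                         seed = 31)
    sf <- suppressWarnings(fit_segmented(d, seed = 1))
    mean(sf$psi_se, na.rm = TRUE)
  }
  expect_gt(se_at(60), se_at(400))
})

test_that("fit_segmented validates its preconditions", {
  d <- make_pwl4_curve(n = 6)
  expect_error(fit_segmented(d), ">= 8 points")
  d2 <- make_pwl4_curve(n = 100, strain_max = 0.5)
  expect_error(fit_segmented(d2, psi0 = c(0.3, 0.4, 0.6)), "span")
  d3 <- make_pwl4_curve(n = 100)
  expect_error(fit_segmented(d3, psi0 = c(0.4, 0.3, 0.6)), "increasing")
})

test_that("smooth wide heels pull the fit into the heel (model mismatch)", {
  # With a C1 heel of substantial width, the SSE-optimal 3-change-point
  # fit places change points inside the transition and the segment-3
  # slope sits well below the true post-heel slope. This is a property
  # of the estimator, documented in the methods vignette.
  spec <- synthetic_spec("bilinear",
                         list(E1 = 20, E2 = 500,
                              heel_start = 0.20, heel_end = 0.40),
                         noise_rel = 0, noise_abs = 0, n_points = 200,
                         seed = 1)
  cv <- gen_bilinear_curve(spec)
  sf <- suppressWarnings(fit_segmented(cv, seed = 1))
  expect_lt(sf$slopes[3], 450)       # truth 500; mismatch bias is large
  expect_true(all(sf$psi < 0.45))    # all change points near/inside heel
})
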