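test_that("generation is deterministic under a fixed seed", {
  spec <- synthetic_spec("blatz", blatz_params(2.09, 12.32), seed = 11)
  expect_identical(gen_blatz_curve(spec)$stress, gen_blatz_curve(spec)$stress)

  bspec <- synthetic_spec("bilinear",
                          list(E1 = 20, E2 = 500,
                               heel_start = 0.2, heel_end = 0.4),
                          seed = 11)
  expect_identical(gen_bilinear_curve(bspec)$stress,
                   gen_bilinear_curve(bspec)$stress)

  # different seeds produce different noise
  bspec2 <- bspec; bspec2$seed <- 12L
  expect_false(identical(gen_bilinear_curve(bspec)$stress,
                         gen_bilinear_curve(bspec2)$stress))

  # and generation does not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(gen_blatz_curve(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("bilinear construction has the stated slopes and C1 heel", {
  spec <- synthetic_spec("bilinear",
                         list(E1 = 20, E2 = 500,
                              heel_start = 0.2, heel_end = 0.4),
                         noise_rel = 0, noise_abs = 0, n_points = 500,
                         seed = 1)
  cv <- gen_bilinear_curve(spec)
  toe <- cv$strain <= 0.2
  post <- cv$strain >= 0.4
  expect_equal(diff(cv$stress[toe]) / diff(cv$strain[toe]),
               rep(20, sum(toe) - 1), tolerance = 1e-9)
  expect_equal(diff(cv$stress[post]) / diff(cv$strain[post]),
               rep(500, sum(post) - 1), tolerance = 1e-9)

  # value and slope continuity at the heel boundaries
  f <- function(s) phantomech:::.bilinear_stress(s, 20, 500, 0.2, 0.4)
  h <- 1e-7
  expect_lt(abs(f(0.2 + 1e-12) - f(0.2 - 1e-12)), 1e-9)
  expect_lt(abs(f(0.4 + 1e-12) - f(0.4 - 1e-12)), 1e-9)
  expect_equal((f(0.2 + h) - f(0.2 - h)) / (2 * h), 20, tolerance = 1e-4)
  expect_equal((f(0.4 + h) - f(0.4 - h)) / (2 * h), 500, tolerance = 1e-4)

  # degenerate heel collapses to a kink
  kspec <- synthetic_spec("bilinear",
                          list(E1 = 20, E2 = 500,
                               heel_start = 0.35, heel_end = 0.35),
                          noise_rel = 0, noise_abs = 0, seed = 1)
  kv <- gen_bilinear_curve(kspec)
  g <- function(s) phantomech:::.bilinear_stress(s, 20, 500, 0.35, 0.35)
  expect_equal(g(0.35), 20 * 0.35)
  expect_equal(g(0.5), 20 * 0.35 + 500 * 0.15)
  expect_equal(kv$stress[1], 0)  # zero stress at zero strain, noise 0
})

test_that("gen_replicate_set builds jittered, independently noisy curves", {
  spec <- synthetic_spec("blatz", blatz_params(1.64, 19.52),
                         n_replicates = 10, seed = 5)
  st <- gen_replicate_set(spec)
  expect_length(st, 10)
  expect_false(identical(st$curves[[1]]$stress, st$curves[[2]]$stress))
  ids <- vapply(st$curves, function(cv) cv$replicate_id, character(1))
  expect_equal(anyDuplicated(ids), 0L)

  # jitter 0 and noise 0 make all replicates identical
  spec0 <- synthetic_spec("blatz", blatz_params(1.64, 19.52),
                          noise_rel = 0, noise_abs = 0, truth_jitter = 0,
                          n_replicates = 3, seed = 5)
  st0 <- gen_replicate_set(spec0)
  expect_identical(st0$curves[[1]]$stress, st0$curves[[3]]$stress)
})

test_that("fixture directories round-trip through the file interface", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec("bilinear",
                         list(E1 = 20, E2 = 500,
                              heel_start = 0.2, heel_end = 0.4),
                         n_replicates = 4, seed = 3)
  st <- gen_replicate_set(spec, material = "SYNTH")
  write_replicate_fixture(st, dir)

  back <- load_replicates(dir, "SYNTH", 0)
  expect_length(back, 4)
  for (i in 1:4) {
    expect_curves_equal(back$curves[[i]], st$curves[[i]])
  }

  truth <- read_truth(dir)
  expect_equal(unname(truth["E1"]), 20)
  expect_equal(unname(truth["E2"]), 500)
})

test_that("synthetic_spec validates its invariants", {
  expect_error(synthetic_spec("bilinear",
                              list(E1 = 20, E2 = 500,
                                   heel_start = 0.5, heel_end = 0.4)),
               "heel")
  expect_error(synthetic_spec("blatz", blatz_params(2, 10), n_points = 4),
               "n_points")
  expect_error(synthetic_spec("blatz", blatz_params(2, 10), noise_rel = -1))
})
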