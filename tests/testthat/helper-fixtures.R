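# Fixture builders and independent oracles shared across test files.

# Exact continuous piecewise-linear curve with three breaks and four
# slopes, through the origin.
pwl4_stress <- function(x, breaks, slopes) {
  v1 <- slopes[1] * breaks[1]
  v2 <- v1 + slopes[2] * (breaks[2] - breaks[1])
  v3 <- v2 + slopes[3] * (breaks[3] - breaks[2])
  ifelse(x <= breaks[1], slopes[1] * x,
    ifelse(x <= breaks[2], v1 + slopes[2] * (x - breaks[1]),
      ifelse(x <= breaks[3], v2 + slopes[3] * (x - breaks[2]),
        v3 + slopes[4] * (x - breaks[3]))))
}

# The canonical four-regime fixture: toe slope E1 = 20, two stiffening
# regimes, segment-3 slope E2 = 500. `slope4` distinct from slope3 keeps
# the third change point identifiable.
make_pwl4_curve <- function(n = 200, strain_max = 0.7,
                            breaks = c(0.20, 0.35, 0.60),
                            slopes = c(20, 150, 500, 800),
                            noise_rel = 0, noise_abs = 0, seed = NULL) {
  x <- seq(0, strain_max, length.out = n)
  y <- pwl4_stress(x, breaks, slopes)
  if (noise_rel > 0 || noise_abs > 0) {
    if (!is.null(seed)) set.seed(seed)
    y <- pmax(y * (1 + rnorm(n, 0, noise_rel)) + rnorm(n, 0, noise_abs), 0)
  }
  data.frame(strain = x, stress = y)
}

# Independent oracle for the segmented fit: exhaustive search over all
# observed-strain breakpoint triples (each of the four segments keeping
# at least two interior points), fitting the continuous piecewise-linear
# model at each triple. Brute force; only for small n.
grid_oracle_sse <- function(x, y) {
  cand <- x[3:(length(x) - 2)]
  nc <- length(cand)
  best <- Inf
  for (i in 1:(nc - 4)) {
    for (j in (i + 2):(nc - 2)) {
      for (k in (j + 2):nc) {
        f <- phantomech:::.pwl_fit(x, y, cand[c(i, j, k)])
        if (f$sse < best) best <- f$sse
      }
    }
  }
  best
}

# A valid random curve for I/O property tests.
random_uc_curve <- function(seed) {
  set.seed(seed)
  n <- sample(8:40, 1)
  strain <- sort(runif(n, 0, 0.75))
  strain <- unique(round(strain, 6))
  while (length(strain) < 4) strain <- c(strain, max(strain) + 0.01)
  stress <- cumsum(abs(rnorm(length(strain), 5, 3)))
  uc_curve(strain, stress, material = "MAT-X", dilution_pct = 10,
           replicate_id = sprintf("r%02d", seed))
}

expect_curves_equal <- function(a, b, tol = 1e-6) {
  expect_equal(a$strain, b$strain, tolerance = tol)
  expect_equal(a$stress, b$stress, tolerance = tol)
}
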