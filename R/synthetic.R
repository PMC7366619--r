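#' Specification of a synthetic uniaxial-compression fixture
#'
#' Describes a stress-strain curve with known ground truth, used to test
#' every pipeline stage without access to measured data. Two kinds are
#' supported: \code{"blatz"} (forward evaluation of the Blatz model) and
#' \code{"bilinear"} (toe slope E1, C1 cubic-Hermite heel, post-heel
#' slope E2 -- the idealized shape of a soft-silicone compression curve).
#' Noise is multiplicative plus additive Gaussian on the stress magnitude,
#' clipped at zero: load-cell error grows with force, with a small
#' absolute floor.
#'
#' @param kind \code{"blatz"} or \code{"bilinear"}.
#' @param truth for \code{"blatz"}: a \code{\link{blatz_params}}; for
#'   \code{"bilinear"}: a list with \code{E1}, \code{E2} (kPa),
#'   \code{heel_start}, \code{heel_end} (strain fractions).
#' @param strain_max maximum strain (default 0.70).
#' @param n_points points on the uniform strain grid (default 200).
#' @param noise_rel multiplicative noise SD (default 0.02).
#' @param noise_abs additive noise SD in kPa (default 0.05).
#' @param n_replicates number of technical replicates (default 5).
#' @param truth_jitter relative SD of the per-replicate jitter applied to
#'   the truth parameters (default 0.02).
#' @param seed integer seed.
#' @return An object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(kind = c("blatz", "bilinear"), truth,
                           strain_max = 0.70, n_points = 200L,
                           noise_rel = 0.02, noise_abs = 0.05,
                           n_replicates = 5L, truth_jitter = 0.02,
                           seed = 1L) {
  kind <- match.arg(kind)
  if (n_points < 8L) stop("n_points must be >= 8", call. = FALSE)
  if (noise_rel < 0 || noise_abs < 0 || truth_jitter < 0) {
    stop("noise and jitter parameters must be >= 0", call. = FALSE)
  }
  if (!(strain_max > 0 && strain_max < 1)) {
    stop("strain_max must be in (0, 1)", call. = FALSE)
  }
  if (kind == "bilinear") {
    stopifnot(is.list(truth),
              all(c("E1", "E2", "heel_start", "heel_end") %in% names(truth)))
    if (!(truth$heel_start > 0 && truth$heel_start <= truth$heel_end &&
          truth$heel_end < strain_max)) {
      stop("need 0 < heel_start <= heel_end < strain_max", call. = FALSE)
    }
  } else {
    stopifnot(inherits(truth, "blatz_params"))
  }
  structure(
    list(kind = kind, truth = truth, strain_max = strain_max,
         n_points = as.integer(n_points), noise_rel = noise_rel,
         noise_abs = noise_abs, n_replicates = as.integer(n_replicates),
         truth_jitter = truth_jitter, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Evaluate R's Mersenne-Twister stream under a local seed, restoring the
# caller's RNG state afterwards: generation is fully deterministic under a
# fixed spec seed and never disturbs user code.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Multiplicative + additive Gaussian noise on a stress magnitude, clipped
# at zero.
.apply_noise <- function(stress, noise_rel, noise_abs) {
  n <- length(stress)
  out <- stress * (1 + stats::rnorm(n, sd = noise_rel)) +
    stats::rnorm(n, sd = noise_abs)
  pmax(out, 0)
}

# Noiseless bilinear (toe / heel / post-heel) stress magnitude. The heel
# is a cubic Hermite blend whose end value makes the slope ramp linearly
# from E1 to E2, giving a C1 curve; heel_start == heel_end degenerates to
# a kink.
.bilinear_stress <- function(strain, E1, E2, h1, h2) {
  v1 <- E1 * h1
  if (h2 > h1) {
    v2 <- v1 + (E1 + E2) / 2 * (h2 - h1)
    t <- pmin(pmax((strain - h1) / (h2 - h1), 0), 1)
    d <- h2 - h1
    # cubic Hermite basis on [0, 1], scaled slopes
    heel <- (2 * t^3 - 3 * t^2 + 1) * v1 + (t^3 - 2 * t^2 + t) * d * E1 +
      (-2 * t^3 + 3 * t^2) * v2 + (t^3 - t^2) * d * E2
  } else {
    v2 <- v1
    heel <- v1
  }
  ifelse(strain <= h1, E1 * strain,
         ifelse(strain >= h2, v2 + E2 * (strain - h2), heel))
}

.synthetic_strain_grid <- function(spec) {
  seq(0, spec$strain_max, length.out = spec$n_points)
}

#' Generate a synthetic Blatz stress-strain curve
#'
#' Evaluates the Blatz model on a uniform strain grid over
#' \code{[0, strain_max]}, takes the stress magnitude, and adds seeded
#' multiplicative + additive Gaussian noise clipped at zero. Deterministic
#' for a fixed spec seed.
#'
#' @param spec a \code{\link{synthetic_spec}} with \code{kind = "blatz"}.
#' @param replicate_id replicate label for the generated curve.
#' @return A \code{\link{uc_curve}} with a \code{truth} attribute.
#' @export
gen_blatz_curve <- function(spec, replicate_id = "r1") {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "blatz")
  strain <- .synthetic_strain_grid(spec)
  stress <- abs(blatz_stress(to_stretch(strain), spec$truth))
  stress <- .with_seed(spec$seed,
                       .apply_noise(stress, spec$noise_rel, spec$noise_abs))
  out <- uc_curve(strain, stress, material = "SYNTH-BLATZ",
                  dilution_pct = 0, replicate_id = replicate_id)
  attr(out, "truth") <- spec$truth
  out
}

#' Generate a synthetic bilinear (toe/heel/post-heel) curve
#'
#' Builds the idealized compression curve of a soft silicone: slope E1 up
#' to \code{heel_start}, a C1 cubic-Hermite heel over
#' \code{[heel_start, heel_end]} whose slope ramps from E1 to E2, and
#' slope E2 beyond; seeded noise as in \code{\link{gen_blatz_curve}}.
#' \code{heel_start == heel_end} degenerates gracefully to a kink.
#'
#' @param spec a \code{\link{synthetic_spec}} with \code{kind = "bilinear"}.
#' @param replicate_id replicate label.
#' @return A \code{\link{uc_curve}} with a \code{truth} attribute.
#' @export
gen_bilinear_curve <- function(spec, replicate_id = "r1") {
  stopifnot(inherits(spec, "synthetic_spec"), spec$kind == "bilinear")
  strain <- .synthetic_strain_grid(spec)
  tr <- spec$truth
  stress <- .bilinear_stress(strain, tr$E1, tr$E2, tr$heel_start,
                             tr$heel_end)
  stress <- .with_seed(spec$seed,
                       .apply_noise(stress, spec$noise_rel, spec$noise_abs))
  out <- uc_curve(strain, stress, material = "SYNTH-BILINEAR",
                  dilution_pct = 0, replicate_id = replicate_id)
  attr(out, "truth") <- tr
  out
}

#' Generate a replicate set with known ground truth
#'
#' Emulates the technical-replicate structure of a mixture: each
#' replicate gets independent noise (seeds \code{seed + i}) and a small
#' independent jitter on the truth parameters (relative SD
#' \code{truth_jitter}, default 2\%) emulating specimen-to-specimen
#' variability.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param material material label for the generated set.
#' @return A \code{\link{replicate_set}} with a \code{truth} attribute
#'   recording the shared truth parameters.
#' @export
gen_replicate_set <- function(spec, material = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(material)) {
    material <- if (spec$kind == "blatz") "SYNTH-BLATZ" else "SYNTH-BILINEAR"
  }
  curves <- vector("list", spec$n_replicates)
  for (i in seq_len(spec$n_replicates)) {
    spec_i <- spec
    spec_i$seed <- spec$seed + i
    if (spec$truth_jitter > 0) {
      jit <- function(v) v * (1 + stats::rnorm(1, sd = spec$truth_jitter))
      spec_i$truth <- .with_seed(spec$seed + 100000L + i, {
        if (spec$kind == "blatz") {
          blatz_params(jit(spec$truth$alpha), jit(spec$truth$gamma))
        } else {
          tr <- spec$truth
          tr$E1 <- jit(tr$E1); tr$E2 <- jit(tr$E2)
          tr
        }
      })
    }
    cv <- if (spec$kind == "blatz") {
      gen_blatz_curve(spec_i, replicate_id = sprintf("r%02d", i))
    } else {
      gen_bilinear_curve(spec_i, replicate_id = sprintf("r%02d", i))
    }
    cv$material <- material
    curves[[i]] <- cv
  }
  out <- replicate_set(curves, material = material, dilution_pct = 0)
  attr(out, "truth") <- spec$truth
  out
}

#' Write a synthetic replicate set as a fixture directory
#'
#' Writes one two-column text file per replicate in the plain-text dialect
#' plus a \code{truth.txt} sidecar (plain \code{key value} lines)
#' recording the ground-truth parameters, so that recovery tests can
#' round-trip through the file-based interface.
#'
#' @param set a \code{\link{replicate_set}} carrying a \code{truth}
#'   attribute (as from \code{\link{gen_replicate_set}}).
#' @param directory target directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_replicate_fixture <- function(set, directory) {
  stopifnot(inherits(set, "replicate_set"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  for (cv in set$curves) {
    fn <- sprintf("%s_%s_%s.txt", cv$material, format(cv$dilution_pct),
                  cv$replicate_id)
    write_curve(cv, file.path(directory, fn))
  }
  truth <- attr(set, "truth")
  if (!is.null(truth)) {
    vals <- unlist(truth)
    writeLines(paste(names(vals), formatC(as.numeric(vals), digits = 12,
                                          format = "g")),
               file.path(directory, "truth.txt"))
  }
  invisible(directory)
}

#' Read the ground-truth sidecar of a fixture directory
#'
#' @param directory fixture directory written by
#'   \code{\link{write_replicate_fixture}}.
#' @return Named numeric vector of truth parameters.
#' @export
read_truth <- function(directory) {
  path <- file.path(directory, "truth.txt")
  if (!file.exists(path)) stop("no truth.txt in ", directory, call. = FALSE)
  lines <- readLines(path)
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  stats::setNames(vapply(parts, function(p) as.numeric(p[2]), numeric(1)),
                  vapply(parts, `[`, character(1), 1))
}
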