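#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of squares taken
#' about the mean of the observations.
#'
#' @param observed observed response values.
#' @param fitted fitted values of equal length.
#' @return \eqn{R^2} as a fraction.
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted) || length(observed) < 2L) {
    stop("observed and fitted must have equal length >= 2", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop("R^2 undefined: observed values are constant", call. = FALSE)
  }
  1 - sum((observed - fitted)^2) / ss_tot
}

# Design matrix of the continuous piecewise-linear model at fixed psi:
# columns 1, x, (x - psi_k)_+.
.pwl_design <- function(x, psi) {
  X <- cbind(1, x)
  for (p in psi) X <- cbind(X, pmax(x - p, 0))
  X
}

# Least-squares fit of the continuous piecewise-linear model at fixed psi.
# Returns intercept, the four segment slopes, fitted values and SSE.
.pwl_fit <- function(x, y, psi) {
  X <- .pwl_design(x, psi)
  fit <- lm.fit(X, y)
  co <- fit$coefficients
  co[is.na(co)] <- 0
  fitted <- drop(X %*% co)
  slopes <- cumsum(co[-1])           # slope of segment k = beta1 + sum(delta_j, j<k)
  list(intercept = unname(co[1]), slopes = unname(slopes),
       fitted = fitted, sse = sum((y - fitted)^2))
}

# One pass of the iterative-linearization change-point search: at the
# current psi regress y on {1, x, (x-psi_k)_+, I(x>psi_k)} and move each
# change point by -gamma_k/delta_k (first-order correction from the gap
# coefficient gamma_k and the slope-change coefficient delta_k), until the
# largest update falls below tol. Returns NULL when psi collapses
# (ordering lost or a change point pushed outside the data range).
.segfit_iterate <- function(x, y, psi, tol = 1e-8, max_iter = 100L) {
  K <- length(psi)
  rng <- range(x)
  # Each of the four segments must hold at least two observations
  # strictly inside it, or the change points are unidentifiable.
  psi_valid <- function(p) {
    if (is.unsorted(p, strictly = TRUE) || p[1] <= rng[1] ||
        p[K] >= rng[2]) {
      return(FALSE)
    }
    counts <- tabulate(findInterval(x, p) + 1L, nbins = K + 1L)
    all(counts >= 2L)
  }
  if (!psi_valid(psi)) return(NULL)
  degenerate <- FALSE
  converged <- FALSE
  n_iter <- 0L
  gamma_se <- rep(NA_real_, K)
  delta <- rep(NA_real_, K)

  # Slope changes below this scale are unidentifiable at double precision
  # and their change points are frozen rather than updated.
  delta_eps <- 1e-8 * (diff(range(y)) / diff(rng) + 1)

  pw_cur <- .pwl_fit(x, y, psi)
  for (it in seq_len(max_iter)) {
    n_iter <- it
    U <- vapply(psi, function(p) pmax(x - p, 0), numeric(length(x)))
    V <- vapply(psi, function(p) as.numeric(x > p), numeric(length(x)))
    X <- cbind(1, x, U, V)
    fit <- lm.fit(X, y)
    co <- fit$coefficients
    delta <- co[2L + seq_len(K)]
    gam <- co[2L + K + seq_len(K)]
    gam[is.na(gam)] <- 0

    frozen <- is.na(delta) | abs(delta) < delta_eps
    degenerate <- any(frozen)
    step <- ifelse(frozen, 0, gam / ifelse(frozen, 1, delta))
    if (all(frozen) || max(abs(step)) < tol) {
      converged <- TRUE
      break
    }
    # Damped update: accept the first halved step that keeps psi valid
    # and does not increase the continuous-fit SSE. The SSE is piecewise
    # smooth in psi with kinks at the data points, so the full
    # first-order step can oscillate around a kink minimum; enforcing
    # monotone descent makes the iteration stop there instead.
    accepted <- FALSE
    for (half in 0:6) {
      psi_new <- psi - step / 2^half
      if (!psi_valid(psi_new)) next
      pw_new <- .pwl_fit(x, y, psi_new)
      if (pw_new$sse <= pw_cur$sse) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) {
      # No descent direction left: at a (possibly kink) local minimum.
      converged <- TRUE
      break
    }
    improvement <- pw_cur$sse - pw_new$sse
    psi <- psi_new
    pw_cur <- pw_new
    if (max(abs(step / 2^half)) < tol ||
        improvement <= 1e-12 * (pw_cur$sse + 1e-12)) {
      converged <- TRUE
      break
    }
  }

  # Standard errors of psi from the final linearized model:
  # SE(psi_k) = SE(gamma_k) / |delta_k|.
  U <- vapply(psi, function(p) pmax(x - p, 0), numeric(length(x)))
  V <- vapply(psi, function(p) as.numeric(x > p), numeric(length(x)))
  X <- cbind(1, x, U, V)
  qf <- lm.fit(X, y)
  rank <- qf$rank
  co <- qf$coefficients
  dof <- length(y) - rank
  if (dof > 0 && !anyNA(co)) {
    s2 <- sum(qf$residuals^2) / dof
    R <- qr.R(qf$qr)
    XtX_inv <- chol2inv(R)
    se_all <- sqrt(pmax(diag(XtX_inv) * s2, 0))
    gamma_se <- se_all[2L + K + seq_len(K)]
    delta_fin <- co[2L + seq_len(K)]
    psi_se <- ifelse(abs(delta_fin) > 1e-12, gamma_se / abs(delta_fin),
                     NA_real_)
  } else {
    psi_se <- rep(NA_real_, K)
  }

  pw <- .pwl_fit(x, y, psi)
  list(psi = unname(psi), psi_se = unname(psi_se), intercept = pw$intercept,
       slopes = pw$slopes, fitted = pw$fitted, sse = pw$sse,
       converged = converged, degenerate = degenerate, n_iter = n_iter)
}

# Try the iteration from a start; on collapse, retry from jittered psi0
# (jitter sd = 5% of the strain range), up to n_jitter times.
.segfit_attempt <- function(x, y, psi0, tol, max_iter, n_jitter = 10L) {
  res <- .segfit_iterate(x, y, psi0, tol, max_iter)
  j <- 0L
  rng <- diff(range(x))
  while (is.null(res) && j < n_jitter) {
    j <- j + 1L
    psi_j <- sort(psi0 + stats::rnorm(length(psi0), sd = 0.05 * rng))
    psi_j <- pmin(pmax(psi_j, min(x) + 1e-6 * rng), max(x) - 1e-6 * rng)
    if (is.unsorted(psi_j, strictly = TRUE)) next
    res <- .segfit_iterate(x, y, psi_j, tol, max_iter)
  }
  res
}

#' Segmented linear regression with three change points
#'
#' Fits a continuous piecewise-linear model with four segments (three
#' change points) to pooled stress-strain data by iterative linearization:
#' at each step, stress is regressed on the strain, hinge terms
#' \eqn{(\epsilon - \psi_k)_+} and gap indicators
#' \eqn{I(\epsilon > \psi_k)}, and each change point is moved by the ratio
#' of the gap coefficient to the slope-change coefficient until the
#' largest move falls below \code{tol}. Bootstrap restarting (residual
#' resampling with fixed strains, \code{n_boot} rounds, keeping the best
#' objective) is used to escape local optima of the nonconvex change-point
#' objective. The change-point standard errors are
#' \eqn{SE(\psi_k) = SE(\hat\gamma_k)/|\hat\delta_k|} from the final
#' linearized model.
#'
#' @param data pooled stress-strain data: a data.frame with columns
#'   \code{strain} and \code{stress} (as from
#'   \code{\link{pool_replicates}}) or a \code{\link{uc_curve}}.
#' @param psi0 initial change points on the strain axis (fractions);
#'   default \code{c(0.30, 0.40, 0.60)}.
#' @param seed integer seed for the bootstrap restarts and jitter.
#' @param n_boot number of bootstrap restart rounds (default 10).
#' @param tol convergence tolerance on the largest change-point move
#'   (default 1e-8).
#' @param max_iter maximum linearization iterations per start
#'   (default 100).
#' @return An object of class \code{segmented_fit} with fields \code{psi},
#'   \code{psi_se}, \code{intercept}, \code{slopes} (four segment slopes,
#'   kPa per unit strain), \code{sse}, \code{r2}, \code{seed},
#'   \code{converged}, \code{degenerate} and \code{n_iter}.
#' @export
fit_segmented <- function(data, psi0 = c(0.30, 0.40, 0.60), seed = 1L,
                          n_boot = 10L, tol = 1e-8, max_iter = 100L) {
  if (inherits(data, "uc_curve")) {
    data <- as.data.frame(data)
  }
  x <- data$strain
  y <- data$stress
  if (length(x) < 8L) {
    stop("need >= 8 points for a three-change-point fit", call. = FALSE)
  }
  if (is.unsorted(psi0, strictly = TRUE)) {
    stop("psi0 must be strictly increasing", call. = FALSE)
  }
  if (max(x) <= max(psi0) || min(x) >= min(psi0)) {
    stop("data must span beyond the initial change points (",
         paste(format(psi0, digits = 3), collapse = ", "), ")",
         call. = FALSE)
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(as.integer(seed))

  # Deterministic multi-start: the supplied psi0 first, then every
  # strictly increasing triple of strain deciles. The change-point
  # objective is nonconvex with many basins; a coarse deterministic
  # start grid plus the bootstrap restarts below reliably reaches the
  # global optimum.
  dec <- unique(stats::quantile(x, seq(0.1, 0.9, by = 0.1), names = FALSE))
  starts <- list(psi0)
  nd <- length(dec)
  for (i in seq_len(nd - 2L)) {
    for (j in seq(i + 1L, nd - 1L)) {
      for (k in seq(j + 1L, nd)) {
        starts[[length(starts) + 1L]] <- dec[c(i, j, k)]
      }
    }
  }
  best <- NULL
  for (s in starts) {
    fs <- .segfit_attempt(x, y, s, tol, max_iter,
                          n_jitter = if (identical(s, psi0)) 10L else 0L)
    if (!is.null(fs) && (is.null(best) || fs$sse < best$sse)) best <- fs
  }
  if (is.null(best)) {
    stop("segmented fit failed to converge from psi0, quantile starts ",
         "and 10 jittered restarts", call. = FALSE)
  }

  # Bootstrap restarting (basin hopping): resample residuals at fixed
  # strains around the current solution, refit on the bootstrap sample,
  # then refit the real data from there; the current state wanders while
  # the best real-data objective is retained.
  if (!best$degenerate && best$sse > 0) {
    current <- best
    for (b in seq_len(n_boot)) {
      res <- y - current$fitted
      yb <- current$fitted + sample(res, replace = TRUE)
      fb <- .segfit_iterate(x, yb, current$psi, tol, max_iter)
      if (is.null(fb)) next
      f2 <- .segfit_iterate(x, y, fb$psi, tol, max_iter)
      if (is.null(f2)) next
      current <- f2
      if (f2$sse < best$sse) best <- f2
    }
  }

  if (best$degenerate) {
    warning("degenerate change points: no identifiable slope change; ",
            "the data are consistent with fewer segments", call. = FALSE)
  }

  structure(
    list(psi = best$psi, psi_se = best$psi_se, intercept = best$intercept,
         slopes = best$slopes, sse = best$sse,
         r2 = r_squared(y, best$fitted), seed = as.integer(seed),
         converged = best$converged, degenerate = best$degenerate,
         n_iter = best$n_iter),
    class = "segmented_fit"
  )
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat("<segmented_fit> seed ", x$seed, if (!x$converged) " (NOT converged)",
      "\n", sep = "")
  cat("  change points: ",
      paste(format(x$psi, digits = 5), collapse = ", "), "\n", sep = "")
  cat("  SE(psi):       ",
      paste(format(x$psi_se, digits = 3), collapse = ", "), "\n", sep = "")
  cat("  segment slopes (kPa): ",
      paste(format(x$slopes, digits = 6), collapse = ", "), "\n", sep = "")
  cat("  R^2 = ", format(x$r2, digits = 6), ", SSE = ",
      format(x$sse, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Estimate low- and high-strain compressive moduli for one mixture
#'
#' Pools the technical replicates of a mixture (after common truncation),
#' runs \code{\link{fit_segmented}} with \code{n_runs} different random
#' seeds, and averages over runs: the low-strain modulus E1 is the mean
#' slope of the first segment (from 0\% strain to the first change point)
#' and the high-strain modulus E2 is the mean slope of the third segment
#' (between the second and third change points). The fourth segment,
#' beyond the third change point, is fitted and reported but unused. A
#' standalone low-strain linear check (ordinary regression over the toe
#' window capped at \code{cfg$e1_fit_limit_strain}) is reported alongside.
#'
#' @param set a \code{\link{replicate_set}}.
#' @param cfg a \code{\link{preprocess_config}}.
#' @param psi0 initial change points; rescaled proportionally (with a
#'   message) when the data do not span beyond them.
#' @param n_runs number of seeded runs to average (default 10).
#' @param n_boot bootstrap restart rounds per run (default 10).
#' @param base_seed first seed; runs use \code{base_seed ..
#'   base_seed + n_runs - 1}.
#' @return An object of class \code{moduli_estimate} with fields \code{E1},
#'   \code{E2} (kPa), \code{E1_sd}, \code{E2_sd} (across-run dispersion),
#'   \code{psi_mean}, \code{psi_se}, \code{r2}, \code{runs} (the per-run
#'   \code{segmented_fit}s), \code{e1_linear_check}, and mixture metadata.
#' @export
estimate_moduli <- function(set, cfg = preprocess_config(),
                            psi0 = c(0.30, 0.40, 0.60), n_runs = 10L,
                            n_boot = 10L, base_seed = 1L) {
  stopifnot(inherits(set, "replicate_set"))
  set <- common_truncate(set, cfg)
  pooled <- pool_replicates(set)

  if (max(pooled$strain) <= max(psi0)) {
    scale <- 0.95 * max(pooled$strain) / max(psi0)
    psi0 <- psi0 * scale
    message("initial change points rescaled to (",
            paste(format(psi0, digits = 3), collapse = ", "),
            ") to fit the observed strain range")
  }

  seeds <- as.integer(base_seed) + seq_len(n_runs) - 1L
  runs <- vector("list", n_runs)
  ok <- logical(n_runs)
  for (i in seq_len(n_runs)) {
    runs[[i]] <- tryCatch(
      fit_segmented(pooled, psi0 = psi0, seed = seeds[i], n_boot = n_boot),
      error = function(e) e)
    ok[i] <- inherits(runs[[i]], "segmented_fit") && runs[[i]]$converged
  }
  if (sum(ok) < ceiling(n_runs / 2)) {
    stop("moduli estimation failed: ", n_runs - sum(ok), " of ", n_runs,
         " segmented-fit runs did not converge", call. = FALSE)
  }
  good <- runs[ok]

  slope1 <- vapply(good, function(f) f$slopes[1], numeric(1))
  slope3 <- vapply(good, function(f) f$slopes[3], numeric(1))
  psi_mat <- t(vapply(good, function(f) f$psi, numeric(3)))
  r2s <- vapply(good, function(f) f$r2, numeric(1))

  # Standalone toe-slope check on the capped low-strain window.
  toe <- pooled[pooled$strain <= cfg$e1_fit_limit_strain, , drop = FALSE]
  e1_check <- if (nrow(toe) >= 2L && stats::var(toe$strain) > 0) {
    lf <- stats::lm(stress ~ strain, data = toe)
    list(slope = unname(stats::coef(lf)[2]),
         r2 = summary(lf)$r.squared, n = nrow(toe))
  } else {
    list(slope = NA_real_, r2 = NA_real_, n = nrow(toe))
  }

  structure(
    list(material = set$material, dilution_pct = set$dilution_pct,
         E1 = mean(slope1), E2 = mean(slope3),
         E1_sd = stats::sd(slope1), E2_sd = stats::sd(slope3),
         psi_mean = colMeans(psi_mat),
         psi_se = apply(psi_mat, 2, stats::sd) / sqrt(nrow(psi_mat)),
         r2 = mean(r2s), runs = good, seeds = seeds[ok],
         n_runs = length(good),
         e1_linear_check = e1_check,
         applied_cutoff = attr(set, "applied_cutoff"),
         coverage_warning = attr(set, "coverage_warning")),
    class = "moduli_estimate"
  )
}

#' @export
print.moduli_estimate <- function(x, ...) {
  cat("<moduli_estimate> ", x$material, " at ", x$dilution_pct, "%\n",
      sep = "")
  cat("  E1 = ", format(x$E1, digits = 6), " kPa (toe),  E2 = ",
      format(x$E2, digits = 6), " kPa (post-heel)\n", sep = "")
  cat("  mean change points: ",
      paste(format(x$psi_mean, digits = 4), collapse = ", "),
      "  (", x$n_runs, " seeded runs, mean R^2 = ",
      format(x$r2, digits = 4), ")\n", sep = "")
  invisible(x)
}
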