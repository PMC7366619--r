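#' Preprocessing configuration
#'
#' Truncation rules applied before moduli estimation. The low-strain (E1)
#' fitting window is capped at \code{e1_fit_limit_strain} (default 0.33,
#' i.e. coefficients of the standalone toe-slope check are determined from
#' measurements up to 33\% compression). A replicate set whose common
#' maximum strain falls below \code{e1_coverage_strain} (default 0.35) is
#' flagged with a coverage warning but still processed, with the common
#' maximum reduced to the smallest per-replicate maximum.
#'
#' @param e1_coverage_strain coverage threshold for the toe-modulus check
#'   (strain fraction, default 0.35).
#' @param e1_fit_limit_strain upper strain bound of the standalone
#'   low-strain linear fit window (default 0.33).
#' @param truncate_to_common_max truncate all replicates at the smallest
#'   per-replicate maximum strain (default TRUE).
#' @return An object of class \code{preprocess_config}.
#' @export
preprocess_config <- function(e1_coverage_strain = 0.35,
                              e1_fit_limit_strain = 0.33,
                              truncate_to_common_max = TRUE) {
  if (!(e1_fit_limit_strain > 0 &&
        e1_fit_limit_strain <= e1_coverage_strain &&
        e1_coverage_strain < 1)) {
    stop("need 0 < e1_fit_limit_strain <= e1_coverage_strain < 1",
         call. = FALSE)
  }
  structure(
    list(e1_coverage_strain = e1_coverage_strain,
         e1_fit_limit_strain = e1_fit_limit_strain,
         truncate_to_common_max = isTRUE(truncate_to_common_max)),
    class = "preprocess_config"
  )
}

#' Convert nominal compressive strain to stretch ratio
#'
#' The stretch ratio is the deformed length over the initial length;
#' under nominal compressive strain \eqn{\epsilon} it is
#' \eqn{\lambda = 1 - \epsilon}, so \eqn{\lambda \in (0, 1]} for
#' admissible compression.
#'
#' @param strain nominal compressive strain fraction(s), in \code{[0, 1)}.
#' @return Stretch ratio(s) \eqn{\lambda}.
#' @examples
#' to_stretch(c(0, 0.33, 0.5)) # 1.00 0.67 0.50
#' @export
to_stretch <- function(strain) {
  if (any(!is.finite(strain)) || any(strain < 0) || any(strain >= 1)) {
    stop("strain must be finite and in [0, 1); strain >= 1 would ",
         "annihilate the specimen", call. = FALSE)
  }
  1 - strain
}

#' Truncate all replicates of a mixture to a common maximum strain
#'
#' If the replicates reached different peak compressions, every curve is
#' truncated at the smallest per-replicate maximum strain so that all
#' replicates cover the same strain range (curves whose sampling grid
#' skips the cutoff get a linearly interpolated end point there, making
#' the operation idempotent). When that common maximum falls
#' below the coverage threshold (default 35\% compression) a warning is
#' emitted and the returned set carries \code{coverage_warning = TRUE};
#' processing continues with the reduced range.
#'
#' @param set a \code{\link{replicate_set}}.
#' @param cfg a \code{\link{preprocess_config}}.
#' @return The truncated \code{replicate_set}, with attributes
#'   \code{applied_cutoff} (the common maximum strain) and
#'   \code{coverage_warning}.
#' @export
common_truncate <- function(set, cfg = preprocess_config()) {
  stopifnot(inherits(set, "replicate_set"),
            inherits(cfg, "preprocess_config"))
  maxima <- vapply(set$curves, function(cv) max(cv$strain), numeric(1))
  if (any(maxima <= 0)) {
    stop("every curve must span strain > 0", call. = FALSE)
  }
  cutoff <- min(maxima)
  coverage_warning <- cutoff < cfg$e1_coverage_strain
  if (coverage_warning) {
    warning("common maximum strain ", format(cutoff, digits = 4),
            " is below the ", format(cfg$e1_coverage_strain, digits = 3),
            " coverage threshold; compression range reduced for all ",
            "replicates", call. = FALSE)
  }
  curves <- set$curves
  if (cfg$truncate_to_common_max) {
    curves <- lapply(curves, function(cv) {
      keep <- cv$strain <= cutoff + 1e-12
      if (sum(keep) < 4L) {
        stop("truncation at strain ", format(cutoff, digits = 4),
             " leaves < 4 points for replicate ", cv$replicate_id,
             call. = FALSE)
      }
      s <- cv$strain[keep]
      y <- cv$stress[keep]
      # Curves sampled on grids that skip the cutoff get an interpolated
      # end point there, so every replicate spans exactly [0, cutoff]
      # and truncation is idempotent.
      if (max(s) < cutoff - 1e-12 && any(cv$strain > cutoff)) {
        y <- c(y, stats::approx(cv$strain, cv$stress, xout = cutoff)$y)
        s <- c(s, cutoff)
      }
      uc_curve(s, y, material = cv$material,
               dilution_pct = cv$dilution_pct,
               replicate_id = cv$replicate_id, strain_rate = cv$strain_rate)
    })
  }
  out <- replicate_set(curves, material = set$material,
                       dilution_pct = set$dilution_pct)
  attr(out, "applied_cutoff") <- cutoff
  attr(out, "coverage_warning") <- coverage_warning
  out
}

#' Pool all replicates of a mixture into one regression data set
#'
#' Concatenates the points of every replicate and sorts them by strain.
#' Duplicate strains across replicates are retained: the result is
#' regression data accumulated over all experiments for the mixture, not a
#' function-valued curve. The pooled data feeds the segmented moduli fit.
#'
#' @param set a \code{\link{replicate_set}}.
#' @return A data.frame with columns \code{strain} and \code{stress},
#'   sorted by strain, with \code{material} and \code{dilution_pct}
#'   attributes.
#' @export
pool_replicates <- function(set) {
  stopifnot(inherits(set, "replicate_set"))
  strain <- unlist(lapply(set$curves, function(cv) cv$strain))
  stress <- unlist(lapply(set$curves, function(cv) cv$stress))
  ord <- order(strain)
  out <- data.frame(strain = strain[ord], stress = stress[ord])
  attr(out, "material") <- set$material
  attr(out, "dilution_pct") <- set$dilution_pct
  out
}
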