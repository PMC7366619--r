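#' Target compressive moduli for mixture screening
#'
#' The elastic targets a candidate phantom material must approach: kidney
#' cortex under uniaxial compression, 20 kPa in low strain and 500 kPa in
#' high strain. The low-strain acceptance interval defaults to the renal
#' cortex Young's-modulus range 13.6--25.8 kPa reported for cylindrical
#' tissue samples.
#'
#' @param E1_target low-strain target modulus, kPa (default 20).
#' @param E2_target high-strain target modulus, kPa (default 500).
#' @param E1_range acceptance interval for E1, kPa
#'   (default \code{c(13.6, 25.8)}).
#' @return An object of class \code{moduli_target}.
#' @export
moduli_target <- function(E1_target = 20, E2_target = 500,
                          E1_range = c(13.6, 25.8)) {
  if (E1_target <= 0 || E2_target <= 0) {
    stop("targets must be positive", call. = FALSE)
  }
  if (E1_target < E1_range[1] || E1_target > E1_range[2]) {
    stop("E1_target must lie within E1_range", call. = FALSE)
  }
  structure(list(E1_target = E1_target, E2_target = E2_target,
                 E1_range = E1_range),
            class = "moduli_target")
}

#' Distance of a mixture's moduli from the screening target
#'
#' Default metric: Euclidean norm of the relative errors,
#' \deqn{d = \sqrt{\left(\frac{E1 - E1^*}{E1^*}\right)^2 +
#'   \left(\frac{E2 - E2^*}{E2^*}\right)^2}.}
#' Relative errors make the metric scale-free across the 25-fold gap
#' between the low- and high-strain targets, and invariant to a common
#' rescaling of units applied to moduli and targets alike. The metric is
#' pluggable via \code{metric}.
#'
#' @param E1,E2 estimated moduli, kPa (positive).
#' @param target a \code{\link{moduli_target}}.
#' @param metric optional function \code{(E1, E2, target) -> score}
#'   replacing the default.
#' @return Nonnegative score; 0 iff the moduli hit the target exactly.
#' @examples
#' moduli_distance(20, 500, moduli_target())   # 0
#' moduli_distance(40, 500, moduli_target())   # 1
#' @export
moduli_distance <- function(E1, E2, target = moduli_target(),
                            metric = NULL) {
  if (any(E1 <= 0) || any(E2 <= 0)) {
    stop("moduli must be positive", call. = FALSE)
  }
  if (!is.null(metric)) return(metric(E1, E2, target))
  sqrt(((E1 - target$E1_target) / target$E1_target)^2 +
         ((E2 - target$E2_target) / target$E2_target)^2)
}

#' Rank silicone mixtures by closeness to the target moduli
#'
#' Orders mixtures by ascending \code{\link{moduli_distance}}; ties are
#' broken by material label, then dilution. Accepts a list of
#' \code{\link{estimate_moduli}} results or a data.frame with columns
#' \code{material}, \code{dilution_pct}, \code{E1}, \code{E2}.
#'
#' @param estimates list of \code{moduli_estimate} objects, or a
#'   data.frame as above.
#' @param target a \code{\link{moduli_target}}.
#' @param metric optional distance override, as in
#'   \code{\link{moduli_distance}}.
#' @return An object of class \code{screening_result}: a data.frame with
#'   one row per mixture (material, dilution_pct, E1, E2, distance,
#'   e1_in_range, rank), sorted by rank.
#' @export
rank_mixtures <- function(estimates, target = moduli_target(),
                          metric = NULL) {
  if (inherits(estimates, "moduli_estimate")) estimates <- list(estimates)
  if (is.data.frame(estimates)) {
    df <- estimates[, c("material", "dilution_pct", "E1", "E2")]
  } else {
    if (!length(estimates)) stop("need at least one estimate", call. = FALSE)
    df <- do.call(rbind, lapply(estimates, function(e) {
      data.frame(material = e$material, dilution_pct = e$dilution_pct,
                 E1 = e$E1, E2 = e$E2)
    }))
  }
  df$distance <- moduli_distance(df$E1, df$E2, target, metric)
  df$e1_in_range <- df$E1 >= target$E1_range[1] &
    df$E1 <= target$E1_range[2]
  ord <- order(df$distance, df$material, df$dilution_pct)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  class(df) <- c("screening_result", "data.frame")
  df
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result> ", nrow(x), " mixture(s), best: ",
      x$material[1], " at ", x$dilution_pct[1], "% (distance ",
      format(x$distance[1], digits = 4), ")\n", sep = "")
  print.data.frame(x, digits = 5)
  invisible(x)
}

# Resolve one mixture entry of a pipeline config into a replicate_set.
.pipeline_load_mixture <- function(mx, base_dir, base_seed) {
  if (!is.null(mx$directory)) {
    dir <- mx$directory
    if (!grepl("^/", dir)) dir <- file.path(base_dir, dir)
    load_replicates(dir, mx$material, mx$dilution_pct)
  } else if (!is.null(mx$synthetic)) {
    sy <- mx$synthetic
    truth <- if (identical(sy$kind, "blatz")) {
      blatz_params(sy$alpha, sy$gamma)
    } else {
      list(E1 = sy$E1, E2 = sy$E2, heel_start = sy$heel_start,
           heel_end = sy$heel_end)
    }
    spec <- synthetic_spec(
      kind = sy$kind, truth = truth,
      strain_max = sy$strain_max %||% 0.70,
      n_points = sy$n_points %||% 200L,
      noise_rel = sy$noise_rel %||% 0.02,
      noise_abs = sy$noise_abs %||% 0.05,
      n_replicates = sy$n_replicates %||% 5L,
      truth_jitter = sy$truth_jitter %||% 0.02,
      seed = sy$seed %||% (base_seed + (mx$seed_offset %||% 0L)))
    st <- gen_replicate_set(spec, material = mx$material)
    st$dilution_pct <- mx$dilution_pct %||% 0
    for (i in seq_along(st$curves)) {
      st$curves[[i]]$dilution_pct <- st$dilution_pct
    }
    st
  } else {
    stop("mixture entry needs either 'directory' or 'synthetic'",
         call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full screening pipeline from a configuration file
#'
#' Executes load (or synthesize) -> preprocess -> segmented moduli ->
#' Blatz fit -> screening for every configured mixture, and writes CSV/TXT
#' reports plus a structured log to the output directory. The
#' configuration is a JSON file (plain structured text) with fields:
#' \describe{
#'   \item{seed}{base seed for all randomness (default 1).}
#'   \item{output_dir}{report directory (relative to the config file).}
#'   \item{targets}{optional \code{E1}, \code{E2}, \code{E1_range}.}
#'   \item{moduli}{optional \code{n_runs}, \code{n_boot}, \code{psi0}.}
#'   \item{mixtures}{array of entries with \code{material},
#'     \code{dilution_pct} and either \code{directory} (replicate files)
#'     or \code{synthetic} (a synthetic-spec block with \code{kind} and
#'     truth parameters).}
#' }
#' Reports: \code{moduli.csv} (per-mixture E1/E2 with change points, SE
#' and R^2), \code{blatz.csv} (per-mixture alpha/gamma mean and SD),
#' \code{quantiles_<material>_<dilution>.txt} (per-parameter quantiles),
#' \code{ranking.csv}, and \code{run_log.txt}. Reruns with the same
#' config and seed are byte-identical.
#'
#' @param config path to a JSON config file, or an equivalent named list.
#' @param output_dir overrides the config's output directory.
#' @return Invisibly, a list with \code{moduli} (per-mixture
#'   \code{moduli_estimate}), \code{blatz} (per-mixture
#'   \code{blatz_summary}), \code{ranking} (a \code{screening_result})
#'   and \code{reports} (paths written).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    base_dir <- dirname(normalizePath(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  } else {
    base_dir <- getwd()
  }
  if (is.null(config$mixtures) || !length(config$mixtures)) {
    stop("pipeline config lists no mixtures", call. = FALSE)
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- output_dir %||% config$output_dir %||% "phantomech_reports"
  if (!grepl("^/", out_dir)) out_dir <- file.path(base_dir, out_dir)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  tg <- config$targets
  target <- moduli_target(tg$E1 %||% 20, tg$E2 %||% 500,
                          unlist(tg$E1_range) %||% c(13.6, 25.8))
  mod_cfg <- config$moduli
  n_runs <- mod_cfg$n_runs %||% 10L
  n_boot <- mod_cfg$n_boot %||% 10L
  psi0 <- unlist(mod_cfg$psi0) %||% c(0.30, 0.40, 0.60)
  cfg <- preprocess_config()

  log_lines <- character(0)
  log_add <- function(...) {
    log_lines[[length(log_lines) + 1L]] <<- paste0(...)
  }
  log_add("phantomech pipeline, seed ", seed)

  moduli <- list()
  blatz <- list()
  for (k in seq_along(config$mixtures)) {
    mx <- config$mixtures[[k]]
    label <- paste0(mx$material, "_", mx$dilution_pct %||% 0)
    stage <- "load"
    res <- tryCatch({
      st <- .pipeline_load_mixture(mx, base_dir, seed)
      log_add("[", label, "] loaded ", length(st$curves), " replicate(s)")
      stage <- "moduli"
      me <- withCallingHandlers(
        estimate_moduli(st, cfg = cfg, psi0 = psi0, n_runs = n_runs,
                        n_boot = n_boot, base_seed = seed),
        warning = function(w) {
          log_add("[", label, "] warning: ", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      log_add("[", label, "] E1 = ", format(me$E1, digits = 6),
              " kPa, E2 = ", format(me$E2, digits = 6),
              " kPa (R^2 = ", format(me$r2, digits = 4), ")")
      stage <- "blatz"
      fits <- lapply(st$curves, function(cv)
        suppressWarnings(fit_blatz(cv)))
      bs <- summarize_blatz(fits)
      log_add("[", label, "] alpha = ", format(bs$alpha_mean, digits = 5),
              " (SD ", format(bs$alpha_sd, digits = 3), "), gamma = ",
              format(bs$gamma_mean, digits = 5), " kPa (SD ",
              format(bs$gamma_sd, digits = 3), ")")
      list(me = me, bs = bs)
    }, error = function(e) {
      stop("pipeline stage '", stage, "' failed for mixture ", label,
           ": ", conditionMessage(e), call. = FALSE)
    })
    moduli[[label]] <- res$me
    blatz[[label]] <- res$bs
  }

  ranking <- rank_mixtures(unname(moduli), target)
  log_add("closest mixture: ", ranking$material[1], " at ",
          ranking$dilution_pct[1], "% (distance ",
          format(ranking$distance[1], digits = 5), ")")

  reports <- .write_pipeline_reports(out_dir, moduli, blatz, ranking)
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  reports <- c(reports, file.path(out_dir, "run_log.txt"))

  invisible(list(moduli = moduli, blatz = blatz, ranking = ranking,
                 reports = reports))
}

.fmt_num <- function(x) formatC(x, digits = 8, format = "g")

.write_pipeline_reports <- function(out_dir, moduli, blatz, ranking) {
  paths <- character(0)

  mod_df <- do.call(rbind, lapply(moduli, function(m) {
    data.frame(material = m$material, dilution_pct = m$dilution_pct,
               E1_kPa = .fmt_num(m$E1), E2_kPa = .fmt_num(m$E2),
               psi1 = .fmt_num(m$psi_mean[1]),
               psi2 = .fmt_num(m$psi_mean[2]),
               psi3 = .fmt_num(m$psi_mean[3]),
               psi1_se = .fmt_num(m$psi_se[1]),
               psi2_se = .fmt_num(m$psi_se[2]),
               psi3_se = .fmt_num(m$psi_se[3]),
               r2 = .fmt_num(m$r2))
  }))
  p <- file.path(out_dir, "moduli.csv")
  utils::write.csv(mod_df, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  bl_df <- do.call(rbind, lapply(names(blatz), function(nm) {
    b <- blatz[[nm]]
    m <- moduli[[nm]]
    data.frame(material = m$material, dilution_pct = m$dilution_pct,
               alpha_mean = .fmt_num(b$alpha_mean),
               alpha_sd = .fmt_num(b$alpha_sd),
               gamma_mean = .fmt_num(b$gamma_mean),
               gamma_sd = .fmt_num(b$gamma_sd),
               n_replicates = b$n_replicates)
  }))
  p <- file.path(out_dir, "blatz.csv")
  utils::write.csv(bl_df, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  for (nm in names(blatz)) {
    b <- blatz[[nm]]
    p <- file.path(out_dir, paste0("quantiles_", nm, ".txt"))
    q <- b$quantiles
    lines <- c(paste("parameter", paste(colnames(q), collapse = " ")),
               paste("alpha", paste(.fmt_num(q["alpha", ]), collapse = " ")),
               paste("gamma", paste(.fmt_num(q["gamma", ]), collapse = " ")))
    writeLines(lines, p)
    paths <- c(paths, p)
  }

  rk <- as.data.frame(ranking)
  rk$E1 <- .fmt_num(rk$E1); rk$E2 <- .fmt_num(rk$E2)
  rk$distance <- .fmt_num(rk$distance)
  p <- file.path(out_dir, "ranking.csv")
  utils::write.csv(rk, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  paths
}
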