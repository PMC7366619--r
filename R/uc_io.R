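#' Uniaxial-compression stress-strain curve
#'
#' Container for one technical replicate of a uniaxial-compression (UC)
#' record: paired nominal compressive strain and nominal compressive stress
#' samples, plus mixture metadata. Strain is stored canonically as a
#' dimensionless fraction in \code{[0, 1)}; stress as a positive magnitude
#' in kPa. The constructor canonicalizes its input: points are sorted by
#' strain and rows with exactly duplicated strain are collapsed by
#' averaging their stress.
#'
#' @param strain numeric vector, nominal compressive strain (fraction).
#' @param stress numeric vector, nominal compressive stress magnitude (kPa).
#' @param material material label, e.g. \code{"ECOFLEX-0010"}.
#' @param dilution_pct thinner percentage, 0--75.
#' @param replicate_id replicate label.
#' @param strain_rate crosshead speed in mm/min (default 5).
#' @return An object of class \code{uc_curve}.
#' @examples
#' uc_curve(c(0, 0.1, 0.2, 0.3), c(0, 2, 6, 14))
#' @export
uc_curve <- function(strain, stress, material = NA_character_,
                     dilution_pct = NA_real_, replicate_id = NA_character_,
                     strain_rate = 5) {
  strain <- as.numeric(strain)
  stress <- as.numeric(stress)
  if (length(strain) != length(stress)) {
    stop("strain and stress must have equal length", call. = FALSE)
  }
  if (!all(is.finite(strain)) || !all(is.finite(stress))) {
    stop("strain and stress must be finite", call. = FALSE)
  }
  ord <- order(strain)
  strain <- strain[ord]
  stress <- stress[ord]
  if (anyDuplicated(strain)) {
    stress <- as.numeric(tapply(stress, factor(strain, levels = unique(strain)), mean))
    strain <- unique(strain)
  }
  if (length(strain) < 4L) {
    stop("insufficient data: need >= 4 distinct strain points, got ",
         length(strain), call. = FALSE)
  }
  if (any(strain < 0) || any(strain >= 1)) {
    stop("strain must lie in [0, 1) as a compressive fraction", call. = FALSE)
  }
  if (any(stress < 0)) {
    stop("stress must be a nonnegative magnitude (kPa)", call. = FALSE)
  }
  structure(
    list(strain = strain, stress = stress,
         material = as.character(material),
         dilution_pct = as.numeric(dilution_pct),
         replicate_id = as.character(replicate_id),
         strain_rate = as.numeric(strain_rate)),
    class = "uc_curve"
  )
}

#' @export
print.uc_curve <- function(x, ...) {
  cat("<uc_curve> ", length(x$strain), " points, strain [",
      format(min(x$strain), digits = 4), ", ",
      format(max(x$strain), digits = 4), "], stress up to ",
      format(max(x$stress), digits = 5), " kPa\n", sep = "")
  meta <- c(material = x$material, dilution = x$dilution_pct,
            replicate = x$replicate_id)
  meta <- meta[!is.na(meta)]
  if (length(meta)) {
    cat("  ", paste(names(meta), meta, sep = "=", collapse = "  "), "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
length.uc_curve <- function(x) length(x$strain)

#' @export
as.data.frame.uc_curve <- function(x, ...) {
  data.frame(strain = x$strain, stress = x$stress)
}

#' Set of technical replicates for one silicone mixture
#'
#' Groups all technical replicates (individual \code{\link{uc_curve}}
#' objects) measured for one mixture of a silicone material with a thinner
#' dilution percentage. All curves must share material and dilution, and
#' replicate ids must be unique.
#'
#' @param curves list of \code{uc_curve} objects.
#' @param material mixture material label; defaults to the curves' label.
#' @param dilution_pct thinner percentage; defaults to the curves' value.
#' @return An object of class \code{replicate_set}.
#' @export
replicate_set <- function(curves, material = NULL, dilution_pct = NULL) {
  if (!is.list(curves) || length(curves) < 1L) {
    stop("need at least one curve", call. = FALSE)
  }
  if (!all(vapply(curves, inherits, logical(1), "uc_curve"))) {
    stop("all elements must be uc_curve objects", call. = FALSE)
  }
  mats <- vapply(curves, function(cv) cv$material, character(1))
  dils <- vapply(curves, function(cv) cv$dilution_pct, numeric(1))
  if (is.null(material)) material <- mats[1]
  if (is.null(dilution_pct)) dilution_pct <- dils[1]
  ok_mat <- is.na(mats) | mats == material
  ok_dil <- is.na(dils) | dils == dilution_pct
  if (!all(ok_mat) || !all(ok_dil)) {
    stop("all curves must share material and dilution_pct", call. = FALSE)
  }
  ids <- vapply(curves, function(cv) cv$replicate_id, character(1))
  ids_known <- ids[!is.na(ids)]
  if (anyDuplicated(ids_known)) {
    stop("replicate ids must be unique: ",
         paste(unique(ids_known[duplicated(ids_known)]), collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(material = as.character(material),
         dilution_pct = as.numeric(dilution_pct),
         curves = curves),
    class = "replicate_set"
  )
}

#' @export
print.replicate_set <- function(x, ...) {
  cat("<replicate_set> ", x$material, " at ", x$dilution_pct, "%: ",
      length(x$curves), " replicate(s)\n", sep = "")
  invisible(x)
}

#' @export
length.replicate_set <- function(x) length(x$curves)

# Split a raw text line into numeric-looking fields (whitespace or comma).
.split_fields <- function(line) {
  strsplit(trimws(line), "[,[:space:]]+")[[1]]
}

# Parse metadata from a "<material>_<dilution>_<replicate>.<ext>" filename.
.parse_filename_meta <- function(path) {
  base <- sub("\\.[^.]*$", "", basename(path))
  m <- regmatches(base,
                  regexec("^(.+)_([0-9]+(?:\\.[0-9]+)?)_([^_]+)$", base))[[1]]
  if (length(m) == 4L) {
    list(material = m[2], dilution_pct = as.numeric(m[3]), replicate_id = m[4])
  } else {
    list(material = NA_character_, dilution_pct = NA_real_,
         replicate_id = NA_character_)
  }
}

#' Read a uniaxial-compression record from a plain-text file
#'
#' Reads a two-column plain-text record (nominal strain, nominal stress).
#' Two dialects are accepted: \code{"txt2col"} (whitespace-separated) and
#' \code{"csv"} (comma-separated); in practice any run of whitespace or a
#' comma is accepted as delimiter in either dialect. A single leading
#' header line is auto-detected (first row treated as header iff either
#' field fails numeric parsing). With \code{units = "auto"} the strain
#' column is interpreted as percent when its maximum exceeds 1.5 (the
#' compressive strain fractions of soft silicones never approach 1.5),
#' otherwise as a fraction.
#'
#' The returned curve is canonicalized: sorted by strain, exact-duplicate
#' strain rows collapsed by averaging stress, strain normalized to a
#' fraction. Files containing an unloading segment (strain decreasing in
#' file order) are rejected; truncate such records at peak strain before
#' reading.
#'
#' @param path file to read.
#' @param dialect \code{"txt2col"} or \code{"csv"} (parsing is tolerant to
#'   either delimiter; the dialect matters when writing).
#' @param units \code{"auto"}, \code{"fraction"} or \code{"percent"}.
#' @param material,dilution_pct,replicate_id optional metadata; when
#'   missing they are parsed from a
#'   \code{<material>_<dilution>_<replicate>.<ext>} filename if possible.
#' @param strain_rate crosshead speed, mm/min.
#' @return A \code{\link{uc_curve}}.
#' @export
read_curve <- function(path, dialect = c("txt2col", "csv"),
                       units = c("auto", "fraction", "percent"),
                       material = NULL, dilution_pct = NULL,
                       replicate_id = NULL, strain_rate = 5) {
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)

  first <- suppressWarnings(as.numeric(.split_fields(lines[1])))
  has_header <- length(first) < 2L || anyNA(first[1:2])
  data_lines <- if (has_header) lines[-1] else lines
  start_line <- if (has_header) 2L else 1L

  n <- length(data_lines)
  if (n < 4L) {
    stop("insufficient data in ", path, ": ", n,
         " data rows found, need >= 4", call. = FALSE)
  }
  strain <- numeric(n)
  stress <- numeric(n)
  for (i in seq_len(n)) {
    f <- suppressWarnings(as.numeric(.split_fields(data_lines[i])))
    if (length(f) < 2L || anyNA(f[1:2])) {
      stop("malformed row at line ", start_line + i - 1L, " of ", path,
           ": '", data_lines[i], "'", call. = FALSE)
    }
    strain[i] <- f[1]
    stress[i] <- f[2]
  }
  if (units == "auto") {
    units <- if (max(strain) > 1.5) "percent" else "fraction"
  }
  if (units == "percent") strain <- strain / 100

  # Collapse exact duplicates in file order, then require a loading ramp:
  # strictly increasing strain. A decrease signals an unloading segment.
  keep_strain <- unique(strain)
  if (length(keep_strain) < length(strain)) {
    agg <- tapply(stress, factor(strain, levels = keep_strain), mean)
    strain <- keep_strain
    stress <- as.numeric(agg)
  }
  if (is.unsorted(strain, strictly = TRUE)) {
    stop("non-monotone strain in ", path,
         ": record appears to contain an unloading segment; ",
         "truncate the data at peak strain and re-read", call. = FALSE)
  }

  meta <- .parse_filename_meta(path)
  if (is.null(material)) material <- meta$material
  if (is.null(dilution_pct)) dilution_pct <- meta$dilution_pct
  if (is.null(replicate_id)) replicate_id <- meta$replicate_id

  uc_curve(strain, stress, material = material, dilution_pct = dilution_pct,
           replicate_id = replicate_id, strain_rate = strain_rate)
}

#' Write a uniaxial-compression record to a plain-text file
#'
#' Inverse of \code{\link{read_curve}}: writes the two-column dialect
#' (\code{"txt2col"}: whitespace-separated with a \code{strain stress}
#' header; \code{"csv"}: comma-separated with a \code{strain,stress}
#' header). Values are written with 9 significant digits so that a
#' write/read round trip reproduces the curve to at least 6 significant
#' digits. Missing target directories are created.
#'
#' @param curve a \code{\link{uc_curve}}.
#' @param path target file.
#' @param dialect \code{"txt2col"} or \code{"csv"}.
#' @param units \code{"fraction"} (as stored) or \code{"percent"}
#'   (strain values multiplied by 100 on output).
#' @return Invisibly, \code{path}.
#' @export
write_curve <- function(curve, path, dialect = c("txt2col", "csv"),
                        units = c("fraction", "percent")) {
  stopifnot(inherits(curve, "uc_curve"))
  dialect <- match.arg(dialect)
  units <- match.arg(units)
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  strain <- curve$strain
  if (units == "percent") strain <- strain * 100
  sep <- if (dialect == "csv") "," else " "
  header <- paste("strain", "stress", sep = sep)
  body <- paste(formatC(strain, digits = 9, format = "g"),
                formatC(curve$stress, digits = 9, format = "g"),
                sep = sep)
  ok <- tryCatch({
    writeLines(c(header, body), con = path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop("cannot write ", path, ": ", conditionMessage(ok), call. = FALSE)
  }
  invisible(path)
}

#' Load all technical replicates for one mixture from a directory
#'
#' Reads every file in \code{directory} matching the
#' \code{<material>_<dilution>_<replicate>.<ext>} pattern for the given
#' mixture, in lexicographic filename order, and assembles a
#' \code{\link{replicate_set}}.
#'
#' @param directory directory holding replicate files.
#' @param material material label used in the filenames.
#' @param dilution_pct dilution percentage used in the filenames.
#' @param units passed to \code{\link{read_curve}}.
#' @return A \code{\link{replicate_set}}.
#' @export
load_replicates <- function(directory, material, dilution_pct,
                            units = "auto") {
  pattern <- paste0("^", material, "_",
                    sub("\\.", "\\\\.", format(dilution_pct)),
                    "_[^_]+\\.(txt|csv|dat)$")
  files <- sort(list.files(directory, pattern = pattern, full.names = TRUE))
  if (!length(files)) {
    stop("no replicate files for ", material, " at ", dilution_pct,
         "% in ", directory, " (pattern: ", pattern, ")", call. = FALSE)
  }
  curves <- vector("list", length(files))
  for (i in seq_along(files)) {
    curves[[i]] <- tryCatch(
      read_curve(files[i], units = units, material = material,
                 dilution_pct = dilution_pct),
      error = function(e) {
        stop("failed to read replicate file ", files[i], ": ",
             conditionMessage(e), call. = FALSE)
      })
  }
  replicate_set(curves, material = material, dilution_pct = dilution_pct)
}
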