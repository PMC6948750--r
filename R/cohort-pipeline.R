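#' Canonical cohort column names
#'
#' The canonical per-subject record layout: subject id, eye, two keratometry
#' readings, three pachymetry readings, three Goldmann readings, three
#' contour-tonometer readings and their quality grades. A column-mapping
#' config translates arbitrary source layouts (e.g. a deposited workbook)
#' into these names.
#'
#' @return Character vector of canonical column names.
#' @export
cohort_columns <- function() {
  c("subject_id", "eye",
    paste0("ccc_", 1:2),
    paste0("cct_", 1:3),
    paste0("iopg_", 1:3),
    paste0("pdct_", 1:3),
    paste0("pdct_q_", 1:3))
}

required_cohort_columns <- function() {
  setdiff(cohort_columns(), paste0("pdct_q_", 1:3))
}

#' Read a column-mapping config file
#'
#' Plain-text `key = value` lines mapping canonical field names (see
#' [cohort_columns()]) to source column names, plus the unit keys
#' `ccc_unit` (`mm` or `diopter`) and `cct_unit` (`um` or `mm`). Lines
#' starting with `#` and blank lines are ignored.
#'
#' @param path Path to the config file.
#' @return Named character vector.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path))
    stop("configuration error: mapping file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad))
    stop("configuration error: malformed mapping line(s): ",
         paste(lines[bad], collapse = "; "), call. = FALSE)
  vals <- trimws(vapply(kv, `[[`, "", 2L))
  names(vals) <- trimws(vapply(kv, `[[`, "", 1L))
  vals
}

#' Load a clinical cohort file
#'
#' Reads per-subject records from CSV (header row required) or XLSX (first
#' worksheet by default), applies the column mapping, converts units
#' (micrometre pachymetry to mm at estimation time; dioptre keratometry to
#' radius via `R = 337.5 / K`), and returns one record per row. Rows with
#' non-numeric measurement cells are skipped and reported with their row
#' numbers.
#'
#' @param path CSV or XLSX file.
#' @param mapping Named character vector mapping canonical names to source
#'   column names, or the path of a mapping config file (see
#'   [read_mapping()]). `NULL` means the file already uses canonical names
#'   with `ccc_unit = "mm"`, `cct_unit = "um"`.
#' @param sheet Worksheet (XLSX only).
#' @return List of `subject_record` objects; skipped row numbers in
#'   attribute `skipped`.
#' @export
load_cohort <- function(path, mapping = NULL, sheet = 1) {
  if (!file.exists(path))
    stop("I/O error: file not found: ", path, call. = FALSE)
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping) &&
      is.null(names(mapping)))
    mapping <- read_mapping(mapping)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE))
      stop("reading XLSX requires the readxl package", call. = FALSE)
    as.data.frame(readxl::read_excel(path, sheet = sheet),
                  stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  }
  ccc_unit <- "mm"
  cct_unit <- "um"
  if (!is.null(mapping)) {
    ccc_unit <- if (!is.na(mapping["ccc_unit"])) unname(mapping["ccc_unit"]) else "mm"
    cct_unit <- if (!is.na(mapping["cct_unit"])) unname(mapping["cct_unit"]) else "um"
    map <- mapping[names(mapping) %in% cohort_columns()]
    missing_src <- setdiff(unname(map), names(raw))
    if (length(missing_src))
      stop("configuration error: mapped column(s) absent from file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    for (canon in names(map)) names(raw)[names(raw) == map[[canon]]] <- canon
  }
  missing_cols <- setdiff(required_cohort_columns(), names(raw))
  if (length(missing_cols))
    stop("configuration error: required column(s) missing: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  has_quality <- all(paste0("pdct_q_", 1:3) %in% names(raw))

  numeric_cols <- setdiff(required_cohort_columns(), c("subject_id", "eye"))
  records <- list()
  skipped <- integer(0)
  for (i in seq_len(nrow(raw))) {
    vals <- suppressWarnings(
      vapply(numeric_cols, function(cl) as.numeric(raw[[cl]][i]), numeric(1)))
    if (any(!is.finite(vals)) || any(vals <= 0)) {
      skipped <- c(skipped, i)
      next
    }
    ccc <- vals[paste0("ccc_", 1:2)]
    if (ccc_unit == "diopter") ccc <- keratometry_to_radius(ccc)
    cct <- vals[paste0("cct_", 1:3)]
    if (cct_unit == "mm") cct <- cct * 1000
    qual <- if (has_quality)
      suppressWarnings(as.numeric(unlist(raw[i, paste0("pdct_q_", 1:3)])))
    else rep(1, 3)
    qual[!is.finite(qual)] <- 1
    records[[length(records) + 1L]] <- subject_record(
      subject_id = as.character(raw$subject_id[i]),
      eye = normalize_eye(raw$eye[i]),
      ccc_readings = unname(ccc),
      cct_readings = unname(cct),
      iopg_readings = unname(vals[paste0("iopg_", 1:3)]),
      pdct_readings = unname(vals[paste0("pdct_", 1:3)]),
      pdct_quality = unname(qual))
  }
  if (length(skipped))
    message(length(skipped), " row(s) skipped (non-numeric or non-positive readings): rows ",
            paste(skipped, collapse = ", "))
  structure(records, skipped = skipped)
}

subject_record <- function(subject_id, eye, ccc_readings, cct_readings,
                           iopg_readings, pdct_readings, pdct_quality) {
  stopifnot(all(ccc_readings > 0), all(cct_readings > 0),
            all(iopg_readings > 0), all(pdct_readings > 0),
            length(pdct_quality) == length(pdct_readings))
  structure(list(subject_id = subject_id, eye = eye,
                 ccc_readings = ccc_readings, cct_readings = cct_readings,
                 iopg_readings = iopg_readings, pdct_readings = pdct_readings,
                 pdct_quality = pdct_quality),
            class = "subject_record")
}

normalize_eye <- function(x) {
  x <- tolower(trimws(as.character(x)))
  if (x %in% c("left", "l", "os")) return("left")
  if (x %in% c("right", "r", "od")) return("right")
  stop("row-level parse error: unrecognised eye label: ", x, call. = FALSE)
}

#' Average a subject's repeated readings
#'
#' Applies the contour-tonometer quality filter (readings with a grade worse
#' than `quality_max` are dropped before averaging; grade 1 is best) and
#' takes arithmetic means of the remaining readings per instrument.
#'
#' @param record A `subject_record`.
#' @param quality_max Worst acceptable quality grade (default 3).
#' @return List with `subject_id`, `eye`, `r_mm`, `t_um`, `iopg`, `pdct`
#'   (NA if every contour reading was filtered out) and `pdct_missing`.
#' @export
prepare_subject <- function(record, quality_max = 3) {
  stopifnot(inherits(record, "subject_record"))
  keep <- record$pdct_quality <= quality_max
  pdct <- if (any(keep)) mean(record$pdct_readings[keep]) else NA_real_
  list(subject_id = record$subject_id,
       eye = record$eye,
       r_mm = mean(record$ccc_readings),
       t_um = mean(record$cct_readings),
       iopg = mean(record$iopg_readings),
       pdct = pdct,
       pdct_missing = !any(keep))
}

#' Per-subject model estimates
#'
#' Runs the shell model for one subject's mean readings: coefficients,
#' corrected true IOP, both modulus estimators, and the two stiffness values.
#'
#' @param means Output of [prepare_subject()].
#' @param calib A [calibration_cornea()].
#' @param constants A [model_constants()].
#' @param variant Corrected-IOP variant, see [ioptcalc()].
#' @return One-row data.frame (class `subject_estimate`) with columns
#'   `subject_id`, `eye`, `r_mm`, `t_um`, `b`, `c`, `iopg_mmhg`,
#'   `pdct_mmhg`, `ioptcalc_mmhg`, `ecalc_mpa`, `ecalc_negative`,
#'   `eiopg_mpa`, `eiopg_negative`, `k_calc_nmm`, `k_iopg_nmm`,
#'   `pdct_missing`.
#' @export
estimate_subject <- function(means, calib, constants = model_constants(),
                             variant = c("consistency", "printed")) {
  variant <- match.arg(variant)
  geo <- suppressWarnings(cornea_geometry(means$r_mm, means$t_um))
  coeff <- shell_coefficients(geo, constants)
  iopt_hat <- ioptcalc(means$iopg, coeff, calib, variant = variant)
  e_g <- eiopg(means$iopg, coeff, calib, constants, variant = variant)
  if (!is.na(means$pdct)) {
    e_c <- ecalc(means$iopg, means$pdct, coeff, constants)
    ecalc_val <- e_c$value; ecalc_neg <- e_c$negative_flag
    k_calc <- stiffness(geo$thickness_mm, e_c)
  } else {
    ecalc_val <- NA_real_; ecalc_neg <- NA; k_calc <- NA_real_
  }
  out <- data.frame(subject_id = means$subject_id, eye = means$eye,
                    r_mm = means$r_mm, t_um = means$t_um,
                    b = coeff$b, c = coeff$c,
                    iopg_mmhg = means$iopg, pdct_mmhg = means$pdct,
                    ioptcalc_mmhg = iopt_hat,
                    ecalc_mpa = ecalc_val, ecalc_negative = ecalc_neg,
                    eiopg_mpa = e_g$value, eiopg_negative = e_g$negative_flag,
                    k_calc_nmm = k_calc,
                    k_iopg_nmm = stiffness(geo$thickness_mm, e_g),
                    pdct_missing = means$pdct_missing,
                    stringsAsFactors = FALSE)
  class(out) <- c("subject_estimate", "data.frame")
  out
}

#' Run the full cohort analysis
#'
#' Selects the analysis eye, averages readings with the quality filter,
#' builds the calibration cornea (cohort-mean geometry by default), computes
#' per-subject estimates and the cohort summary.
#'
#' @param records List of `subject_record`s from [load_cohort()].
#' @param eye `"left"` (default), `"right"`, or `"both"`.
#' @param quality_max Contour-tonometer quality cut (default 3).
#' @param calibration `"cohort_mean"` (default: mean curvature and thickness
#'   of the analysed records, recomputed per run) or a numeric
#'   `c(radius_mm, thickness_um)` override.
#' @param constants A [model_constants()].
#' @param variant Corrected-IOP variant, see [ioptcalc()].
#' @param diff_threshold Tonometer-disagreement threshold in mmHg
#'   (default 4).
#' @return List with `estimates` (data.frame, one row per subject),
#'   `summary` (see [summarize_cohort()]), and `calibration`.
#' @export
analyze_cohort <- function(records, eye = c("left", "right", "both"),
                           quality_max = 3, calibration = "cohort_mean",
                           constants = model_constants(),
                           variant = c("consistency", "printed"),
                           diff_threshold = 4) {
  eye <- match.arg(eye)
  variant <- match.arg(variant)
  if (eye != "both")
    records <- Filter(function(r) r$eye == eye, records)
  if (!length(records))
    stop("no records remain after eye selection", call. = FALSE)
  means <- lapply(records, prepare_subject, quality_max = quality_max)
  if (identical(calibration, "cohort_mean")) {
    cal_geo <- suppressWarnings(cornea_geometry(
      mean(vapply(means, `[[`, numeric(1), "r_mm")),
      mean(vapply(means, `[[`, numeric(1), "t_um"))))
  } else {
    stopifnot(is.numeric(calibration), length(calibration) == 2L)
    cal_geo <- suppressWarnings(cornea_geometry(calibration[1], calibration[2]))
  }
  calib <- calibration_cornea(cal_geo, constants)
  est <- do.call(rbind, lapply(means, estimate_subject, calib = calib,
                               constants = constants, variant = variant))
  rownames(est) <- NULL
  list(estimates = est,
       summary = summarize_cohort(est, diff_threshold = diff_threshold),
       calibration = calib)
}

#' Summarize a cohort's estimates
#'
#' Descriptive statistics (mean, sample SD) for the clinical and derived
#' variables, the seven-variable Pearson correlation matrix with stars, the
#' named regressions (Ecalc on IOPG, Eiopg on CCT, Ecalc on CCT),
#' Bland-Altman agreement between the two modulus estimators, and the count
#' of subjects whose tonometers disagree by at least `diff_threshold` mmHg
#' (absolute difference, inclusive). With fewer than 3 subjects only the
#' descriptives are produced; undefined correlations (constant series) are
#' reported as NA.
#'
#' @param estimates data.frame of per-subject estimates
#'   (see [estimate_subject()]).
#' @param diff_threshold Disagreement threshold in mmHg.
#' @return A `cohort_summary` list: `n`, `descriptives` (data.frame of
#'   mean/sd per variable), `correlations`, `regressions`, `bland_altman`,
#'   `paired_iopg_pdct`, `n_diff_ge_threshold`, `diff_threshold`,
#'   `mean_pdct_minus_ioptcalc`, `mean_k_iopg`, `mean_t_times_mean_eiopg`,
#'   `n_negative_ecalc`, `n_negative_eiopg`, `n_pdct_missing`.
#' @export
summarize_cohort <- function(estimates, diff_threshold = 4) {
  stopifnot(is.data.frame(estimates))
  n <- nrow(estimates)
  vars <- c(ccc_mm = "r_mm", cct_um = "t_um", iopg_mmhg = "iopg_mmhg",
            pdct_mmhg = "pdct_mmhg", ioptcalc_mmhg = "ioptcalc_mmhg",
            ecalc_mpa = "ecalc_mpa", eiopg_mpa = "eiopg_mpa",
            k_calc_nmm = "k_calc_nmm", k_iopg_nmm = "k_iopg_nmm")
  desc <- data.frame(
    variable = names(vars),
    mean = vapply(vars, function(v) mean(estimates[[v]], na.rm = TRUE), numeric(1)),
    sd = vapply(vars, function(v) stats::sd(estimates[[v]], na.rm = TRUE), numeric(1)),
    row.names = NULL)
  out <- list(n = n, descriptives = desc, diff_threshold = diff_threshold)
  d <- estimates$iopg_mmhg - estimates$pdct_mmhg
  out$n_diff_ge_threshold <- sum(abs(d) >= diff_threshold, na.rm = TRUE)
  out$mean_pdct_minus_ioptcalc <-
    mean(estimates$pdct_mmhg - estimates$ioptcalc_mmhg, na.rm = TRUE)
  out$mean_k_iopg <- mean(estimates$k_iopg_nmm, na.rm = TRUE)
  out$mean_t_times_mean_eiopg <-
    mean(estimates$t_um / 1000, na.rm = TRUE) * mean(estimates$eiopg_mpa, na.rm = TRUE)
  out$n_negative_ecalc <- sum(estimates$ecalc_negative, na.rm = TRUE)
  out$n_negative_eiopg <- sum(estimates$eiopg_negative, na.rm = TRUE)
  out$n_pdct_missing <- sum(estimates$pdct_missing, na.rm = TRUE)
  if (n >= 3L) {
    seven <- data.frame(CCC = estimates$r_mm, IOPG = estimates$iopg_mmhg,
                        PDCT = estimates$pdct_mmhg,
                        IOPTcalc = estimates$ioptcalc_mmhg,
                        CCT = estimates$t_um, Ecalc = estimates$ecalc_mpa,
                        Eiopg = estimates$eiopg_mpa)
    out$correlations <- tryCatch(correlation_matrix(seven),
                                 error = function(e) NULL)
    out$regressions <- list(
      ecalc_on_iopg = try_fit(estimates$iopg_mmhg, estimates$ecalc_mpa),
      eiopg_on_cct = try_fit(estimates$t_um, estimates$eiopg_mpa),
      ecalc_on_cct = try_fit(estimates$t_um, estimates$ecalc_mpa))
    out$bland_altman <- tryCatch(
      bland_altman(estimates$ecalc_mpa, estimates$eiopg_mpa),
      error = function(e) NULL)
    out$paired_iopg_pdct <- tryCatch(
      paired_t(estimates$iopg_mmhg, estimates$pdct_mmhg),
      error = function(e) NULL)
  }
  structure(out, class = "cohort_summary")
}

try_fit <- function(x, y) {
  tryCatch(ols_fit(x, y), error = function(e) NULL)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d)\n", x$n))
  d <- x$descriptives
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %-14s %8.4f (SD %.4f)\n", d$variable[i], d$mean[i], d$sd[i]))
  cat(sprintf("  |IOPG - PDCT| >= %g mmHg: %d subject(s)\n",
              x$diff_threshold, x$n_diff_ge_threshold))
  cat(sprintf("  mean(PDCT - IOPTcalc): %.4f mmHg\n", x$mean_pdct_minus_ioptcalc))
  cat(sprintf("  negative-flagged: Ecalc %d, Eiopg %d; PDCT-missing: %d\n",
              x$n_negative_ecalc, x$n_negative_eiopg, x$n_pdct_missing))
  if (!is.null(x$correlations)) {
    cat("\n")
    print(x$correlations)
  }
  if (!is.null(x$regressions)) {
    for (nm in names(x$regressions)) {
      if (is.null(x$regressions[[nm]])) next
      cat("  ", nm, ": ", sep = "")
      print(x$regressions[[nm]])
    }
  }
  if (!is.null(x$bland_altman)) {
    cat("  Ecalc vs Eiopg ")
    print(x$bland_altman)
  }
  invisible(x)
}

#' Write cohort analysis results
#'
#' Writes the per-subject table (full double precision, unit-suffixed column
#' names), a structured plain-text summary report, and optionally the
#' error-decomposition curves. Output is deterministic for fixed inputs.
#'
#' @param estimates Per-subject estimates data.frame.
#' @param summary A `cohort_summary`.
#' @param out_dir Output directory (created if absent).
#' @param curves Optional curves data.frame from [error_decomposition()].
#' @return Invisibly, the paths written.
#' @export
write_results <- function(estimates, summary, out_dir, curves = NULL) {
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  paths <- c(subjects = file.path(out_dir, "subjects.csv"),
             summary = file.path(out_dir, "summary.txt"))
  fmt <- estimates
  for (cl in names(fmt))
    if (is.double(fmt[[cl]])) fmt[[cl]] <- sprintf("%.17g", fmt[[cl]])
  utils::write.csv(fmt, paths[["subjects"]], row.names = FALSE, quote = FALSE)
  writeLines(utils::capture.output(print(summary)), paths[["summary"]])
  if (!is.null(curves)) {
    paths <- c(paths, curves = file.path(out_dir, "error_curves.csv"))
    utils::write.csv(curves, paths[["curves"]], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}
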