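#' Specification of a synthetic clinical cohort
#'
#' Parameters of the forward observation model used to generate synthetic
#' cohorts. Per-subject latent state (curvature, thickness, true IOP, true
#' modulus) is drawn from truncated normals — thickness and curvature jointly
#' bivariate normal with correlation `corr_t_r` — and instrument readings are
#' the model-predicted values plus zero-mean Gaussian noise, replicated per
#' the clinical protocol (2 keratometry, 3 pachymetry, 3 Goldmann, 3 contour
#' readings with quality grades). The Goldmann reading mean is the forward
#' shell prediction [predicted_iopg()] for the subject's latent state; the
#' contour reading mean is the latent true IOP.
#'
#' Population defaults are the reference cohort moments (curvature
#' 7.75 +/- 0.26 mm, thickness 549.9 +/- 32.8 um, true IOP
#' 16.89 +/- 2.49 mmHg, modulus 0.29 +/- 0.06 MPa, corr(t, R) = 0.23).
#' Instrument noise SDs default to a quarter of each population SD — the
#' population SDs describe between-subject spread, of which instrument noise
#' is a minor share.
#'
#' @param n_subjects Number of subjects (two eyes each).
#' @param r_mean,r_sd Curvature mean and SD, mm.
#' @param t_mean,t_sd Central thickness mean and SD, um.
#' @param iop_mean,iop_sd True IOP mean and SD, mmHg.
#' @param e_mean,e_sd True modulus mean and SD, MPa.
#' @param corr_t_r Correlation between thickness and curvature.
#' @param ker_noise_mm,pachy_noise_um,goldmann_noise_mmhg,pdct_noise_mmhg
#'   Per-reading instrument noise SDs.
#' @param quality_probs Probabilities of contour quality grades 1--5.
#' @param seed Integer seed fixing all randomness (used by
#'   [generate_cohort()]).
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_subjects = 100,
                           r_mean = 7.75, r_sd = 0.26,
                           t_mean = 549.9, t_sd = 32.8,
                           iop_mean = 16.89, iop_sd = 2.49,
                           e_mean = 0.29, e_sd = 0.06,
                           corr_t_r = 0.23,
                           ker_noise_mm = 0.25 * 0.26,
                           pachy_noise_um = 0.25 * 32.8,
                           goldmann_noise_mmhg = 0.25 * 2.71,
                           pdct_noise_mmhg = 0.25 * 2.49,
                           quality_probs = c(0.38, 0.38, 0.19, 0.03, 0.02),
                           seed = 1L) {
  spec <- list(n_subjects = n_subjects, r_mean = r_mean, r_sd = r_sd,
               t_mean = t_mean, t_sd = t_sd, iop_mean = iop_mean,
               iop_sd = iop_sd, e_mean = e_mean, e_sd = e_sd,
               corr_t_r = corr_t_r, ker_noise_mm = ker_noise_mm,
               pachy_noise_um = pachy_noise_um,
               goldmann_noise_mmhg = goldmann_noise_mmhg,
               pdct_noise_mmhg = pdct_noise_mmhg,
               quality_probs = quality_probs / sum(quality_probs),
               seed = seed)
  validate_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_spec <- function(spec) {
  if (spec$n_subjects < 1)
    stop("spec error: `n_subjects` must be >= 1", call. = FALSE)
  sds <- c(spec$r_sd, spec$t_sd, spec$iop_sd, spec$e_sd, spec$ker_noise_mm,
           spec$pachy_noise_um, spec$goldmann_noise_mmhg, spec$pdct_noise_mmhg)
  if (any(sds < 0))
    stop("spec error: standard deviations must be >= 0", call. = FALSE)
  if (abs(spec$corr_t_r) >= 1)
    stop("spec error: |corr_t_r| must be < 1", call. = FALSE)
  if (length(spec$quality_probs) != 5L || any(spec$quality_probs < 0))
    stop("spec error: `quality_probs` must be 5 non-negative values", call. = FALSE)
  invisible(spec)
}

#' Read a synthetic-cohort spec from a plain-text file
#'
#' `key = value` lines with the argument names of [synthetic_spec()];
#' `quality_probs` as comma-separated values. Unspecified keys keep their
#' defaults.
#'
#' @param path Path to the spec file.
#' @return A `synthetic_spec`.
#' @export
read_synthetic_spec <- function(path) {
  kv <- read_mapping(path)
  args <- list()
  for (key in names(kv)) {
    if (!key %in% names(formals(synthetic_spec)))
      stop("spec error: unknown key: ", key, call. = FALSE)
    val <- suppressWarnings(as.numeric(strsplit(kv[[key]], ",")[[1]]))
    if (any(!is.finite(val)))
      stop("spec error: non-numeric value for key: ", key, call. = FALSE)
    args[[key]] <- val
  }
  do.call(synthetic_spec, args)
}

#' Draw latent per-subject true states
#'
#' Thickness and curvature from a bivariate normal with the spec correlation;
#' true IOP and true modulus from independent normals. Draws violating
#' validity (non-positive values, thickness not below the radius) are
#' resampled with a bounded number of retries.
#'
#' @param spec A [synthetic_spec()].
#' @param max_retries Resampling rounds before giving up.
#' @return data.frame with columns `subject_id`, `r_mm`, `t_um`, `true_iop`,
#'   `true_e`.
#' @export
draw_true_states <- function(spec, max_retries = 100L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_subjects
  sigma <- matrix(c(spec$t_sd^2,
                    spec$corr_t_r * spec$t_sd * spec$r_sd,
                    spec$corr_t_r * spec$t_sd * spec$r_sd,
                    spec$r_sd^2), 2, 2)
  draw_block <- function(m) {
    tr <- MASS::mvrnorm(m, mu = c(spec$t_mean, spec$r_mean), Sigma = sigma)
    tr <- matrix(tr, ncol = 2)
    data.frame(r_mm = tr[, 2], t_um = tr[, 1],
               true_iop = stats::rnorm(m, spec$iop_mean, spec$iop_sd),
               true_e = stats::rnorm(m, spec$e_mean, spec$e_sd))
  }
  valid <- function(d)
    d$r_mm > 0 & d$t_um > 0 & d$t_um / 1000 < d$r_mm &
      d$true_iop > 0 & d$true_e > 0
  out <- draw_block(n)
  retries <- 0L
  while (any(!valid(out))) {
    retries <- retries + 1L
    if (retries > max_retries)
      stop("generation error: could not draw valid states (spec too wide?)",
           call. = FALSE)
    bad <- which(!valid(out))
    out[bad, ] <- draw_block(length(bad))
  }
  out$subject_id <- sprintf("S%03d", seq_len(n))
  out[c("subject_id", "r_mm", "t_um", "true_iop", "true_e")]
}

#' Simulate instrument readings for latent states
#'
#' Applies the forward observation model to each latent state, for both eyes
#' (shared latent state per subject, independent instrument noise per eye):
#' the Goldmann reading mean is the shell-model prediction for the subject's
#' geometry, modulus and true IOP; the contour-tonometer mean is the true
#' IOP itself. Replicate counts follow the clinical protocol.
#'
#' @param states data.frame from [draw_true_states()].
#' @param spec A [synthetic_spec()].
#' @param constants A [model_constants()].
#' @param eyes Eyes to simulate (default both).
#' @return data.frame in the canonical cohort layout ([cohort_columns()]).
#' @export
simulate_readings <- function(states, spec, constants = model_constants(),
                              eyes = c("left", "right")) {
  stopifnot(inherits(spec, "synthetic_spec"), is.data.frame(states))
  rows <- list()
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    geo <- suppressWarnings(cornea_geometry(st$r_mm, st$t_um))
    coeff <- shell_coefficients(geo, constants)
    iopg_true <- predicted_iopg(st$true_iop, st$true_e, coeff, constants)
    for (eye in eyes) {
      row <- data.frame(subject_id = st$subject_id, eye = eye,
                        stringsAsFactors = FALSE)
      ccc <- st$r_mm + stats::rnorm(2, 0, spec$ker_noise_mm)
      cct <- st$t_um + stats::rnorm(3, 0, spec$pachy_noise_um)
      iopg <- iopg_true + stats::rnorm(3, 0, spec$goldmann_noise_mmhg)
      pdct <- st$true_iop + stats::rnorm(3, 0, spec$pdct_noise_mmhg)
      qual <- sample(1:5, 3, replace = TRUE, prob = spec$quality_probs)
      row[paste0("ccc_", 1:2)] <- as.list(ccc)
      row[paste0("cct_", 1:3)] <- as.list(cct)
      row[paste0("iopg_", 1:3)] <- as.list(iopg)
      row[paste0("pdct_", 1:3)] <- as.list(pdct)
      row[paste0("pdct_q_", 1:3)] <- as.list(qual)
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a complete synthetic cohort
#'
#' Seeds the generator, draws latent states and simulates readings in one
#' deterministic pass.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Seed overriding `spec$seed`.
#' @param constants A [model_constants()].
#' @return List with `states` (latent truth) and `readings` (canonical
#'   cohort data.frame).
#' @export
generate_cohort <- function(spec = synthetic_spec(), seed = spec$seed,
                            constants = model_constants()) {
  if (!is.null(seed)) set.seed(seed)
  states <- draw_true_states(spec)
  readings <- simulate_readings(states, spec, constants)
  list(states = states, readings = readings)
}

#' Convert a canonical readings data.frame to subject records
#'
#' In-memory equivalent of writing the readings to CSV and calling
#' [load_cohort()]; used by the recovery study to avoid file round-trips.
#'
#' @param readings data.frame in the canonical layout.
#' @return List of `subject_record`s.
#' @export
records_from_frame <- function(readings) {
  lapply(seq_len(nrow(readings)), function(i) {
    r <- readings[i, ]
    subject_record(
      subject_id = as.character(r$subject_id), eye = normalize_eye(r$eye),
      ccc_readings = as.numeric(r[paste0("ccc_", 1:2)]),
      cct_readings = as.numeric(r[paste0("cct_", 1:3)]),
      iopg_readings = as.numeric(r[paste0("iopg_", 1:3)]),
      pdct_readings = as.numeric(r[paste0("pdct_", 1:3)]),
      pdct_quality = as.numeric(r[paste0("pdct_q_", 1:3)]))
  })
}

#' Write a synthetic cohort to CSV
#'
#' Full double precision (17 significant digits) so a reload reproduces the
#' generated values bit-for-bit; byte-identical output for identical input.
#'
#' @param readings Canonical readings data.frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_synthetic_cohort <- function(readings, path) {
  fmt <- readings
  for (cl in names(fmt))
    if (is.double(fmt[[cl]])) fmt[[cl]] <- sprintf("%.17g", fmt[[cl]])
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parameter-recovery study
#'
#' Generates replicate synthetic cohorts, runs the full analysis pipeline on
#' each (left eye, default quality filter, cohort-mean calibration), and
#' compares the recovered two-tonometer modulus against each subject's
#' latent true modulus.
#'
#' @param spec A [synthetic_spec()].
#' @param n_replicates Number of replicate cohorts.
#' @param seed Master seed; replicate r uses `seed + r`.
#' @param constants A [model_constants()].
#' @return data.frame with one row per replicate: `replicate`, `n`,
#'   `bias_ecalc`, `rmse_ecalc`, `bias_eiopg`, `rmse_eiopg`.
#' @export
recovery_study <- function(spec = synthetic_spec(), n_replicates = 10,
                           seed = spec$seed, constants = model_constants()) {
  stopifnot(n_replicates >= 1)
  rows <- lapply(seq_len(n_replicates), function(r) {
    cohort <- generate_cohort(spec, seed = seed + r, constants = constants)
    recs <- records_from_frame(cohort$readings)
    res <- analyze_cohort(recs, eye = "left", constants = constants)
    est <- merge(res$estimates, cohort$states, by = "subject_id")
    d_calc <- est$ecalc_mpa - est$true_e
    d_iopg <- est$eiopg_mpa - est$true_e
    data.frame(replicate = r, n = nrow(est),
               bias_ecalc = mean(d_calc, na.rm = TRUE),
               rmse_ecalc = sqrt(mean(d_calc^2, na.rm = TRUE)),
               bias_eiopg = mean(d_iopg, na.rm = TRUE),
               rmse_eiopg = sqrt(mean(d_iopg^2, na.rm = TRUE)))
  })
  do.call(rbind, rows)
}
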