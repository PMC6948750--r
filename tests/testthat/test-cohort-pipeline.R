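test_that("a canonical CSV loads into subject records with unit conversion downstream", {
  path <- write_cohort_fixture(list(
    fixture_row("S001", "left", cct = c(549.9, 549.9, 549.9)),
    fixture_row("S002", "right")))
  recs <- load_cohort(path)
  expect_length(recs, 2)
  expect_identical(recs[[1]]$eye, "left")
  m <- prepare_subject(recs[[1]])
  expect_equal(m$t_um, 549.9)
  est <- estimate_subject(m, calibration_cornea(cornea_geometry(7.75, 549.9)))
  expect_equal(est$t_um, 549.9)       # stored in micrometres
  expect_equal(est$r_mm, 7.75)        # CCC readings (7.7, 7.8) average to 7.75
})

test_that("column mapping renames source columns and converts dioptre keratometry", {
  df <- data.frame(id = "P1", side = "OS",
                   K1 = 43.55, K2 = 43.55,
                   pachy1 = 548, pachy2 = 550, pachy3 = 552,
                   gat1 = 15, gat2 = 15, gat3 = 15,
                   dct1 = 17, dct2 = 17, dct3 = 17,
                   q1 = 1, q2 = 1, q3 = 2)
  src <- tempfile(fileext = ".csv")
  utils::write.csv(df, src, row.names = FALSE, quote = FALSE)
  mapping <- c(subject_id = "id", eye = "side",
               ccc_1 = "K1", ccc_2 = "K2",
               cct_1 = "pachy1", cct_2 = "pachy2", cct_3 = "pachy3",
               iopg_1 = "gat1", iopg_2 = "gat2", iopg_3 = "gat3",
               pdct_1 = "dct1", pdct_2 = "dct2", pdct_3 = "dct3",
               pdct_q_1 = "q1", pdct_q_2 = "q2", pdct_q_3 = "q3",
               ccc_unit = "diopter")
  recs <- load_cohort(src, mapping = mapping)
  expect_length(recs, 1)
  expect_equal(recs[[1]]$ccc_readings, rep(337.5 / 43.55, 2), tolerance = 1e-12)
  expect_equal(recs[[1]]$ccc_readings[1], 7.750, tolerance = 1e-3)
  expect_identical(recs[[1]]$eye, "left")
})

test_that("mapping config files parse and missing columns are configuration errors", {
  cfg <- tempfile()
  writeLines(c("# comment", "subject_id = id", "ccc_unit = diopter"), cfg)
  parsed <- read_mapping(cfg)
  expect_identical(unname(parsed["subject_id"]), "id")
  path <- write_cohort_fixture(list(fixture_row()))
  df <- utils::read.csv(path)
  df$iopg_1 <- NULL
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(load_cohort(path), "configuration error.*iopg_1")
  expect_error(load_cohort(tempfile()), "not found")
})

test_that("malformed rows are skipped and reported with row numbers", {
  path <- write_cohort_fixture(list(
    fixture_row("S001"),
    fixture_row("S002", iopg = c("bad", 15, 15)),
    fixture_row("S003")))
  expect_message(recs <- load_cohort(path), "rows 2")
  expect_length(recs, 2)
  expect_identical(attr(recs, "skipped"), 2L)
})

test_that("quality filter drops poor contour readings before averaging", {
  rec <- corneamech:::subject_record("S1", "left", c(7.7, 7.8),
                                     c(548, 550, 552), c(15, 15, 15),
                                     c(16, 17, 30), c(1, 2, 5))
  m <- prepare_subject(rec, quality_max = 3)
  expect_equal(m$pdct, 16.5)
  m_strict <- prepare_subject(rec, quality_max = 0)
  expect_true(m_strict$pdct_missing)
  expect_true(is.na(m_strict$pdct))
  # Eiopg still computable when every contour reading is filtered out
  est <- estimate_subject(m_strict,
                          calibration_cornea(cornea_geometry(7.75, 550)))
  expect_false(is.na(est$eiopg_mpa))
  expect_true(is.na(est$ecalc_mpa))
})

test_that("a subject at the calibration geometry satisfies the calibration identity", {
  cal <- calibration_cornea(cornea_geometry(7.75, 549.9))
  m <- list(subject_id = "S1", eye = "left", r_mm = 7.75, t_um = 549.9,
            iopg = 15.06, pdct = 16.89, pdct_missing = FALSE)
  est <- estimate_subject(m, cal)
  expect_equal(est$ioptcalc_mmhg, 15.06, tolerance = 1e-12)
  expect_equal(est$ecalc_mpa, 0.234438196970689, tolerance = 1e-12)
  expect_equal(est$eiopg_mpa, 0.277524999302144, tolerance = 1e-12)
  expect_equal(est$k_iopg_nmm, est$t_um / 1000 * est$eiopg_mpa,
               tolerance = 1e-15)
  expect_equal(est$k_calc_nmm, est$t_um / 1000 * est$ecalc_mpa,
               tolerance = 1e-15)
})

test_that("eye selection restricts the analysis to one eye per subject", {
  rows <- c(lapply(1:4, function(i) fixture_row(sprintf("S%03d", i), "left")),
            lapply(1:4, function(i) fixture_row(sprintf("S%03d", i), "right")))
  recs <- load_cohort(write_cohort_fixture(rows))
  res_l <- analyze_cohort(recs, eye = "left")
  res_b <- analyze_cohort(recs, eye = "both")
  expect_equal(res_l$summary$n, 4)
  expect_equal(res_b$summary$n, 8)
  expect_error(analyze_cohort(list()), "no records")
})

test_that("cohort-mean calibration is recomputed per run; explicit override honoured", {
  co <- generate_cohort(synthetic_spec(n_subjects = 12, seed = 5))
  recs <- records_from_frame(co$readings)
  res <- analyze_cohort(recs, eye = "left")
  expect_equal(res$calibration$geometry$radius_mm,
               mean(res$estimates$r_mm), tolerance = 1e-12)
  res2 <- analyze_cohort(recs, eye = "left", calibration = c(7.8, 540))
  expect_equal(res2$calibration$geometry$thickness_mm, 0.540,
               tolerance = 1e-12)
})

test_that("summary: degenerate cohorts, inclusive disagreement count, stiffness means", {
  cal <- calibration_cornea(cornea_geometry(7.75, 550))
  m <- list(subject_id = "S1", eye = "left", r_mm = 7.75, t_um = 550,
            iopg = 15, pdct = 19, pdct_missing = FALSE)
  one <- estimate_subject(m, cal)
  dup <- do.call(rbind, replicate(5, one, simplify = FALSE))
  s <- summarize_cohort(dup)
  expect_equal(s$n, 5)
  expect_true(all(s$descriptives$sd == 0))
  expect_null(s$correlations)   # undefined on constant series, reported as absent
  expect_equal(s$n_diff_ge_threshold, 5)  # |15 - 19| = 4 counts (inclusive)
  # mean stiffness equals mean(t * E); mean(t) * mean(E) reported alongside
  co <- generate_cohort(synthetic_spec(n_subjects = 20, seed = 9))
  res <- analyze_cohort(records_from_frame(co$readings))
  expect_equal(res$summary$mean_k_iopg,
               mean(res$estimates$t_um / 1000 * res$estimates$eiopg_mpa),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(res$summary$mean_k_iopg,
                                res$summary$mean_t_times_mean_eiopg)))
})

test_that("results round-trip: the written per-subject CSV reproduces the summary exactly", {
  co <- generate_cohort(synthetic_spec(n_subjects = 15, seed = 21))
  res <- analyze_cohort(records_from_frame(co$readings))
  out <- tempfile()
  paths <- write_results(res$estimates, res$summary, out)
  expect_true(file.exists(paths[["subjects"]]))
  expect_true(file.exists(paths[["summary"]]))
  back <- utils::read.csv(paths[["subjects"]])
  s2 <- summarize_cohort(back)
  expect_equal(s2$descriptives, res$summary$descriptives, tolerance = 1e-15)
  expect_equal(s2$n_diff_ge_threshold, res$summary$n_diff_ge_threshold)
  # deterministic byte-stable output
  out2 <- tempfile()
  write_results(res$estimates, res$summary, out2)
  expect_identical(readLines(paths[["subjects"]]),
                   readLines(file.path(out2, "subjects.csv")))
})
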