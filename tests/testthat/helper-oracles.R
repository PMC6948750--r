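# Brute-force moment oracles, coded independently of the package's
# stats wrappers (sums only, no cor.test/lm/t.test).

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  r <- sxy / sqrt(sxx * syy)
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2), t = t, n = n)
}

oracle_ols <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  t <- slope / se
  list(slope = slope, intercept = intercept,
       p = 2 * stats::pt(-abs(t), df = n - 2))
}

oracle_bland_altman <- function(a, b) {
  d <- a - b
  m <- (a + b) / 2
  n <- length(d)
  bias <- sum(d) / n
  sd_d <- sqrt(sum((d - bias)^2) / (n - 1))
  fit <- oracle_ols(m, d)
  list(bias = bias, sd_diff = sd_d,
       loa_low = bias - 1.96 * sd_d, loa_high = bias + 1.96 * sd_d,
       prop_slope = fit$slope, prop_p = fit$p)
}

oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  md <- sum(d) / n
  sd_d <- sqrt(sum((d - md)^2) / (n - 1))
  t <- md / (sd_d / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1), mean_diff = md)
}

# Independently factored evaluation of the shell coefficients (different
# algebraic arrangement from the package's).
oracle_b <- function(R, t, nu = 0.49, f = 0.6) {
  f * pi * (R^2 - R * t / 2) / t^2 * sqrt((1 - nu) * (1 + nu))
}
oracle_c <- function(R, t, nu = 0.49, A = 7.35) {
  (2 * pi / ((1 - nu) * A)) * (R^2 / t - R / 2)
}

random_geometry <- function() {
  cornea_geometry(runif(1, 6.8, 9.2), runif(1, 380, 720))
}

# Minimal canonical cohort CSV fixture: one data row per (subject, eye).
write_cohort_fixture <- function(rows, path = tempfile(fileext = ".csv")) {
  df <- do.call(rbind, lapply(rows, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

fixture_row <- function(subject_id = "S001", eye = "left",
                        ccc = c(7.7, 7.8), cct = c(548, 550, 551.7),
                        iopg = c(15, 15, 15.18), pdct = c(16.8, 16.9, 16.97),
                        q = c(1, 2, 3)) {
  out <- list(subject_id = subject_id, eye = eye)
  out[paste0("ccc_", 1:2)] <- as.list(ccc)
  out[paste0("cct_", 1:3)] <- as.list(cct)
  out[paste0("iopg_", 1:3)] <- as.list(iopg)
  out[paste0("pdct_", 1:3)] <- as.list(pdct)
  out[paste0("pdct_q_", 1:3)] <- as.list(q)
  out
}
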