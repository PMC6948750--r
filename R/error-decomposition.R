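#' Goldmann error attributable to corneal thickness alone
#'
#' Holds the modulus and the true IOP fixed at calibration-cornea anchors and
#' varies central thickness over a grid, recording how far the predicted
#' Goldmann reading moves from its value at the calibration thickness.
#' Positive error means over-reading relative to the calibration cornea; the
#' curve is zero at the calibration thickness by construction and increases
#' with thickness under the default parse (thicker corneas over-read).
#'
#' @param grid_um Strictly increasing central-thickness grid in micrometres.
#' @param calib A [calibration_cornea()].
#' @param fixed_modulus Modulus (MPa) held constant along the curve.
#' @param true_iop True IOP anchor in mmHg.
#' @param constants A [model_constants()].
#' @return An `error_curve`: data.frame with columns `cct_um` and
#'   `error_mmhg`, attribute `label = "effect_of_cct"`.
#' @examples
#' cal <- calibration_cornea(cornea_geometry(7.75, 549.9))
#' eg <- eiopg(15.06, cal$coefficients, cal)
#' crv <- effect_of_cct_curve(seq(450, 650, 5), cal, eg$value, 16.89)
#' curve_span(crv)  # ~8.35 mmHg over the 200 um range
#' @export
effect_of_cct_curve <- function(grid_um, calib, fixed_modulus, true_iop,
                                constants = model_constants()) {
  check_grid(grid_um)
  stopifnot(inherits(calib, "calibration_cornea"))
  if (fixed_modulus <= 0 || true_iop <= 0)
    stop("`fixed_modulus` and `true_iop` must be > 0", call. = FALSE)
  r_c <- calib$geometry$radius_mm
  t_c_um <- 1000 * calib$geometry$thickness_mm
  pred <- vapply(grid_um, function(t_um) {
    geo <- suppressWarnings(cornea_geometry(r_c, t_um))
    predicted_iopg(true_iop, fixed_modulus,
                   shell_coefficients(geo, constants), constants)
  }, numeric(1))
  ref <- predicted_iopg(true_iop, fixed_modulus, calib$coefficients, constants)
  error_curve(grid_um, pred - ref, "effect_of_cct", t_c_um)
}

#' Goldmann error attributable to modulus variation alone
#'
#' Holds geometry at the calibration cornea and varies the modulus with
#' thickness through a supplied mapping (typically a cohort-fitted linear
#' trend of modulus on CCT, see [fit_modulus_mapping()]), recording the shift
#' in predicted Goldmann reading relative to the calibration thickness.
#'
#' Two propagation routes are provided. `"model"` pushes the modulus change
#' through the forward shell relation at the calibration coefficients
#' (`7500 * dE / Bc` mmHg per MPa). `"regression"` converts the modulus
#' change to a Goldmann change through an empirical modulus-on-IOPG
#' regression slope (`dE / slope`), the route used when anchoring the
#' decomposition to a cohort's own observed modulus--pressure relation; it
#' requires `e_on_iopg_slope`.
#'
#' @param grid_um Strictly increasing CCT grid in micrometres.
#' @param calib A [calibration_cornea()].
#' @param modulus_of_cct Function mapping CCT in micrometres to modulus in
#'   MPa, defined over the whole grid.
#' @param true_iop True IOP anchor in mmHg (used by the `"model"` route).
#' @param constants A [model_constants()].
#' @param propagation `"model"` (default) or `"regression"`.
#' @param e_on_iopg_slope Slope of the modulus-on-Goldmann regression
#'   (MPa per mmHg); required for `propagation = "regression"`.
#' @return An `error_curve` labelled `"effect_of_e"`.
#' @examples
#' cal <- calibration_cornea(cornea_geometry(7.75, 549.9))
#' flat <- function(t_um) rep(0.29, length(t_um))
#' crv <- effect_of_e_curve(seq(450, 650, 5), cal, flat, 16.89)
#' curve_span(crv)  # 0: constant modulus produces no error
#' @export
effect_of_e_curve <- function(grid_um, calib, modulus_of_cct, true_iop,
                              constants = model_constants(),
                              propagation = c("model", "regression"),
                              e_on_iopg_slope = NULL) {
  propagation <- match.arg(propagation)
  check_grid(grid_um)
  stopifnot(inherits(calib, "calibration_cornea"), is.function(modulus_of_cct))
  t_c_um <- 1000 * calib$geometry$thickness_mm
  e_grid <- modulus_of_cct(grid_um)
  e_ref <- modulus_of_cct(t_c_um)
  if (any(!is.finite(e_grid)) || !is.finite(e_ref))
    stop("configuration error: `modulus_of_cct` is not defined over the grid",
         call. = FALSE)
  err <- switch(propagation,
    model = {
      pred <- predicted_iopg(true_iop, e_grid, calib$coefficients, constants)
      ref <- predicted_iopg(true_iop, e_ref, calib$coefficients, constants)
      pred - ref
    },
    regression = {
      if (is.null(e_on_iopg_slope) || !is.finite(e_on_iopg_slope) ||
          e_on_iopg_slope == 0)
        stop("configuration error: `e_on_iopg_slope` required and nonzero for regression propagation",
             call. = FALSE)
      (e_grid - e_ref) / e_on_iopg_slope
    }
  )
  error_curve(grid_um, err, "effect_of_e", t_c_um)
}

#' Net Goldmann error curve
#'
#' Combines the thickness- and modulus-driven component curves into the net
#' Goldmann error over the grid. `mode = "sum"` adds the components
#' pointwise. `mode = "empirical"` instead evaluates the cohort's own
#' observed error: an OLS fit of (IOPG - PDCT) on CCT, evaluated on the grid
#' and centred at the calibration thickness, which requires `cohort`.
#'
#' @param cct_curve,e_curve `error_curve` objects on identical grids.
#' @param mode `"sum"` or `"empirical"`.
#' @param cohort For `mode = "empirical"`: data.frame with columns `cct_um`,
#'   `iopg`, `pdct`.
#' @return An `error_curve` labelled `"net"`.
#' @export
net_error_curve <- function(cct_curve, e_curve, mode = c("sum", "empirical"),
                            cohort = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(cct_curve, "error_curve"), inherits(e_curve, "error_curve"))
  if (!isTRUE(all.equal(cct_curve$cct_um, e_curve$cct_um)))
    stop("invalid input: component curves are on different grids", call. = FALSE)
  t_c_um <- attr(cct_curve, "calibration_cct_um")
  if (mode == "sum") {
    err <- cct_curve$error_mmhg + e_curve$error_mmhg
  } else {
    if (is.null(cohort) ||
        !all(c("cct_um", "iopg", "pdct") %in% names(cohort)))
      stop("`cohort` with columns cct_um, iopg, pdct required for empirical mode",
           call. = FALSE)
    fit <- stats::lm(I(iopg - pdct) ~ cct_um, data = cohort)
    pred <- stats::predict(fit, newdata = data.frame(cct_um = cct_curve$cct_um))
    ref <- stats::predict(fit, newdata = data.frame(cct_um = t_c_um))
    err <- as.numeric(pred - ref)
  }
  error_curve(cct_curve$cct_um, err, "net", t_c_um)
}

#' Span of an error curve
#'
#' Maximum minus minimum error over the grid (mmHg, non-negative); the
#' summary by which the thickness- and modulus-driven error magnitudes are
#' reported.
#'
#' @param curve An `error_curve`.
#' @return Span in mmHg.
#' @export
curve_span <- function(curve) {
  stopifnot(inherits(curve, "error_curve"))
  if (nrow(curve) == 0L)
    stop("invalid input: empty error curve", call. = FALSE)
  max(curve$error_mmhg) - min(curve$error_mmhg)
}

#' Fit a linear modulus-on-thickness mapping from a cohort
#'
#' OLS fit of per-subject modulus on CCT, returned as a function usable as
#' the `modulus_of_cct` argument of [effect_of_e_curve()].
#'
#' @param cct_um Per-subject CCT in micrometres.
#' @param modulus_mpa Per-subject modulus in MPa.
#' @return A function mapping CCT (um) to modulus (MPa), with the fitted
#'   slope (MPa per um) and intercept attached as attributes `slope` and
#'   `intercept`.
#' @export
fit_modulus_mapping <- function(cct_um, modulus_mpa) {
  stopifnot(length(cct_um) == length(modulus_mpa), length(cct_um) >= 3L)
  fit <- stats::lm(modulus_mpa ~ cct_um)
  a <- unname(stats::coef(fit)[1]); b <- unname(stats::coef(fit)[2])
  f <- function(t_um) a + b * t_um
  attr(f, "slope") <- b
  attr(f, "intercept") <- a
  f
}

#' Three-curve Goldmann error decomposition
#'
#' Convenience wrapper producing the thickness-driven, modulus-driven and net
#' error curves on one grid, as a single wide data.frame ready for CSV
#' export.
#'
#' @param calib A [calibration_cornea()].
#' @param modulus_of_cct Mapping for the modulus-driven curve.
#' @param fixed_modulus,true_iop Anchors for the thickness-driven curve.
#' @param grid_um CCT grid in micrometres (default 450--650 by 5).
#' @param constants A [model_constants()].
#' @param net_mode,cohort Passed to [net_error_curve()].
#' @param propagation,e_on_iopg_slope Passed to [effect_of_e_curve()].
#' @return data.frame with columns `cct_um`, `effect_of_cct_mmhg`,
#'   `effect_of_e_mmhg`, `net_mmhg`; spans attached as attribute `spans`.
#' @export
error_decomposition <- function(calib, modulus_of_cct, fixed_modulus,
                                true_iop, grid_um = seq(450, 650, by = 5),
                                constants = model_constants(),
                                net_mode = "sum", cohort = NULL,
                                propagation = "model",
                                e_on_iopg_slope = NULL) {
  cct <- effect_of_cct_curve(grid_um, calib, fixed_modulus, true_iop, constants)
  eff_e <- effect_of_e_curve(grid_um, calib, modulus_of_cct, true_iop,
                             constants, propagation = propagation,
                             e_on_iopg_slope = e_on_iopg_slope)
  net <- net_error_curve(cct, eff_e, mode = net_mode, cohort = cohort)
  out <- data.frame(cct_um = grid_um,
                    effect_of_cct_mmhg = cct$error_mmhg,
                    effect_of_e_mmhg = eff_e$error_mmhg,
                    net_mmhg = net$error_mmhg)
  attr(out, "spans") <- c(effect_of_cct = curve_span(cct),
                          effect_of_e = curve_span(eff_e),
                          net = curve_span(net))
  out
}

error_curve <- function(grid_um, errors, label, calibration_cct_um) {
  if (any(!is.finite(errors)))
    stop("error curve contains non-finite values", call. = FALSE)
  structure(data.frame(cct_um = grid_um, error_mmhg = errors),
            class = c("error_curve", "data.frame"),
            label = label, calibration_cct_um = calibration_cct_um)
}

check_grid <- function(grid_um) {
  if (length(grid_um) == 0L || any(!is.finite(grid_um)))
    stop("invalid grid: empty or non-finite", call. = FALSE)
  if (any(diff(grid_um) <= 0))
    stop("invalid grid: CCT values must be strictly increasing", call. = FALSE)
  if (any(grid_um <= 0))
    stop("invalid grid: CCT values must be positive", call. = FALSE)
  invisible(grid_um)
}
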