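#' Corneal geometry
#'
#' The geometry of the corneal shell: anterior radius of curvature and central
#' thickness, both stored internally in millimetres. Values outside the
#' clinically plausible ranges (R in 6.5--9.5 mm, t in 0.35--0.75 mm) trigger
#' a warning but are not rejected, so the model can be exercised off the
#' physiological range.
#'
#' @param radius_mm Anterior radius of curvature R in mm (keratometric
#'   dioptres convert as R = 337.5 / K).
#' @param thickness Central corneal thickness t; micrometres by default
#'   (clinical pachymetry convention).
#' @param thickness_unit `"um"` (default) or `"mm"`.
#' @return An object of class `cornea_geometry` with fields `radius_mm` and
#'   `thickness_mm`.
#' @examples
#' cornea_geometry(7.75, 549.9)           # thickness in micrometres
#' cornea_geometry(7.75, 0.5499, "mm")    # identical geometry
#' @export
cornea_geometry <- function(radius_mm, thickness, thickness_unit = c("um", "mm")) {
  thickness_unit <- match.arg(thickness_unit)
  stopifnot(is.numeric(radius_mm), length(radius_mm) == 1L,
            is.numeric(thickness), length(thickness) == 1L,
            is.finite(radius_mm), is.finite(thickness))
  t_mm <- if (thickness_unit == "um") thickness / 1000 else thickness
  if (radius_mm <= 0 || t_mm <= 0)
    stop("invalid geometry: radius and thickness must be > 0", call. = FALSE)
  if (t_mm >= radius_mm)
    stop("invalid geometry: thickness must be smaller than the radius", call. = FALSE)
  if (radius_mm < 6.5 || radius_mm > 9.5)
    warning(sprintf("radius %.3f mm outside the plausible clinical range [6.5, 9.5]",
                    radius_mm), call. = FALSE)
  if (t_mm < 0.35 || t_mm > 0.75)
    warning(sprintf("thickness %.4f mm outside the plausible clinical range [0.35, 0.75]",
                    t_mm), call. = FALSE)
  structure(list(radius_mm = radius_mm, thickness_mm = t_mm),
            class = "cornea_geometry")
}

#' @export
print.cornea_geometry <- function(x, ...) {
  cat(sprintf("Cornea: R = %.3f mm, t = %.1f um\n",
              x$radius_mm, 1000 * x$thickness_mm))
  invisible(x)
}

#' Convert keratometric dioptres to radius of curvature
#'
#' Standard keratometric conversion using the 337.5 calibration index.
#'
#' @param k_diopters Keratometry reading in dioptres.
#' @return Radius of curvature in mm.
#' @examples
#' keratometry_to_radius(43.55)  # ~7.750 mm
#' @export
keratometry_to_radius <- function(k_diopters) {
  if (any(k_diopters <= 0, na.rm = TRUE))
    stop("keratometry readings must be > 0 dioptres", call. = FALSE)
  337.5 / k_diopters
}

#' Goldmann-reading shell coefficient B
#'
#' Dimensionless coefficient multiplying the Goldmann tonometer reading in the
#' thin spherical shell applanation model,
#' \deqn{B = 0.6\,\pi R (R - t/2) \sqrt{1-\nu^2} / t^2.}
#' `B` is strictly decreasing in thickness at fixed radius. The `parse`
#' argument selects between the default algebraic reading of the model and two
#' rejected alternatives retained for the parse-audit harness (see
#' [audit_parses()]).
#'
#' @param geometry A [cornea_geometry()].
#' @param constants A [model_constants()].
#' @param parse Algebraic variant: `"default"` (the supported model),
#'   `"no_sqrt"` (the nu factor entering as `1 - nu^2` without the square
#'   root), or `"squared_chord"` (`(R - t)^2` in place of `R(R - t/2)`).
#' @return The dimensionless coefficient.
#' @examples
#' b_coefficient(cornea_geometry(7.75, 549.9))  # ~314.79
#' @export
b_coefficient <- function(geometry, constants = model_constants(),
                          parse = c("default", "no_sqrt", "squared_chord")) {
  parse <- match.arg(parse)
  stopifnot(inherits(geometry, "cornea_geometry"),
            inherits(constants, "model_constants"))
  R <- geometry$radius_mm
  t <- geometry$thickness_mm
  nu <- constants$poisson_ratio
  f <- constants$shell_factor
  switch(parse,
    default       = f * pi * R * (R - t / 2) * sqrt(1 - nu^2) / t^2,
    no_sqrt       = f * pi * R * (R - t / 2) * (1 - nu^2) / t^2,
    squared_chord = f * pi * R * (R - t)^2 * sqrt(1 - nu^2) / t^2
  )
}

#' Contour-reading shell coefficient C
#'
#' Dimensionless coefficient multiplying the true (contour-tonometer)
#' intraocular pressure in the shell model,
#' \deqn{C = 2\,\pi R (R - t/2) / ((1-\nu) A t),}
#' with `A` the applanated area. Strictly decreasing in thickness and in `A`.
#'
#' @inheritParams b_coefficient
#' @param parse Algebraic variant: `"default"` (the factor 2 in the
#'   numerator), `"two_nu_denominator"` (`2(1-nu)` wholly in the denominator)
#'   or `"two_nu_numerator"` (`2(1-nu)` wholly in the numerator). The
#'   alternatives are retained only for [audit_parses()].
#' @return The dimensionless coefficient.
#' @examples
#' c_coefficient(cornea_geometry(7.75, 549.9))  # ~176.59
#' @export
c_coefficient <- function(geometry, constants = model_constants(),
                          parse = c("default", "two_nu_denominator",
                                    "two_nu_numerator")) {
  parse <- match.arg(parse)
  stopifnot(inherits(geometry, "cornea_geometry"),
            inherits(constants, "model_constants"))
  R <- geometry$radius_mm
  t <- geometry$thickness_mm
  nu <- constants$poisson_ratio
  A <- constants$applanation_area
  base <- pi * R * (R - t / 2) / (A * t)
  switch(parse,
    default            = 2 * base / (1 - nu),
    two_nu_denominator = base / (2 * (1 - nu)),
    two_nu_numerator   = base * 2 * (1 - nu)
  )
}

#' Shell coefficients of a cornea
#'
#' Computes the (B, C) coefficient pair of a cornea under the active model
#' constants.
#'
#' @inheritParams b_coefficient
#' @param b_parse,c_parse Parse variants forwarded to [b_coefficient()] and
#'   [c_coefficient()].
#' @return An object of class `shell_coefficients` with fields `b` and `c`.
#' @examples
#' shell_coefficients(cornea_geometry(7.75, 549.9))
#' @export
shell_coefficients <- function(geometry, constants = model_constants(),
                               b_parse = "default", c_parse = "default") {
  b <- b_coefficient(geometry, constants, parse = b_parse)
  cc <- c_coefficient(geometry, constants, parse = c_parse)
  structure(list(b = b, c = cc, geometry = geometry),
            class = "shell_coefficients")
}

#' @export
print.shell_coefficients <- function(x, ...) {
  cat(sprintf("Shell coefficients: B = %.4f, C = %.4f\n", x$b, x$c))
  invisible(x)
}

#' Calibration cornea
#'
#' The cornea with average curvature and thickness, for which the Goldmann
#' reading is assumed to equal the true intraocular pressure. Houses the
#' calibration coefficients Bc and Cc computed from its geometry under the
#' active constants.
#'
#' @inheritParams b_coefficient
#' @return An object of class `calibration_cornea` with fields `geometry` and
#'   `coefficients`.
#' @examples
#' calibration_cornea(cornea_geometry(7.75, 549.9))
#' @export
calibration_cornea <- function(geometry, constants = model_constants()) {
  structure(
    list(geometry = geometry,
         coefficients = shell_coefficients(geometry, constants),
         constants = constants),
    class = "calibration_cornea"
  )
}

#' @export
print.calibration_cornea <- function(x, ...) {
  cat("Calibration cornea\n  ")
  print(x$geometry)
  cat(sprintf("  Bc = %.4f, Cc = %.4f\n",
              x$coefficients$b, x$coefficients$c))
  invisible(x)
}

#' Calculated true intraocular pressure from a Goldmann reading
#'
#' Corrects a Goldmann applanation reading for the test cornea's geometry
#' through the shell coefficients, yielding an estimate of the true IOP. Two
#' algebraic variants are provided. The `"consistency"` variant (default),
#' `IOPG (B - C + Cc) / Bc`, gives a corrected pressure that falls as corneal
#' thickness rises — matching the physical direction (Goldmann over-reads
#' thick corneas) and the negative correlation between the corrected pressure
#' and thickness observed in cohorts. The `"printed"` variant,
#' `IOPG (Bc - Cc + C) / B`, is the subscript arrangement as commonly typeset
#' and moves in the opposite direction; it is retained behind this flag. Both
#' reduce to `iopg` when the test cornea equals the calibration cornea.
#'
#' @param iopg Goldmann reading in mmHg (> 0).
#' @param test [shell_coefficients()] of the test cornea.
#' @param calib [shell_coefficients()] of the calibration cornea (or a
#'   [calibration_cornea()]).
#' @param variant `"consistency"` (default) or `"printed"`.
#' @return Calculated true IOP in mmHg.
#' @examples
#' cal <- shell_coefficients(cornea_geometry(7.75, 549.9))
#' thick <- shell_coefficients(cornea_geometry(7.75, 650))
#' ioptcalc(15, thick, cal)                       # below 15: thick cornea
#' ioptcalc(15, thick, cal, variant = "printed")  # the typeset arrangement
#' @export
ioptcalc <- function(iopg, test, calib, variant = c("consistency", "printed")) {
  variant <- match.arg(variant)
  calib <- as_shell_coefficients(calib)
  test <- as_shell_coefficients(test)
  stopifnot(is.numeric(iopg), all(is.finite(iopg)))
  if (any(iopg <= 0))
    stop("`iopg` must be > 0 mmHg", call. = FALSE)
  denom <- if (variant == "printed") test$b else calib$b
  if (denom <= 0)
    stop("degenerate model: non-positive denominator coefficient", call. = FALSE)
  if (variant == "printed") {
    iopg * (calib$b - calib$c + test$c) / test$b
  } else {
    iopg * (test$b - test$c + calib$c) / calib$b
  }
}

as_shell_coefficients <- function(x) {
  if (inherits(x, "calibration_cornea")) return(x$coefficients)
  if (inherits(x, "shell_coefficients")) return(x)
  stop("expected `shell_coefficients` or `calibration_cornea`", call. = FALSE)
}

#' Young's modulus from paired tonometry (Ecalc)
#'
#' The two-tonometer modulus estimator:
#' \deqn{E_{calc} = (B\,IOPG - C\,IOPT) / 7500 \quad [MPa],}
#' with IOPT the contour-tonometer (true) pressure. Linear in both pressures.
#' A non-positive result is retained and flagged, never clamped.
#'
#' @param iopg Goldmann reading, mmHg (> 0).
#' @param iopt True / contour-tonometer pressure, mmHg (> 0); either a
#'   measured value or the output of [ioptcalc()].
#' @param test [shell_coefficients()] of the test cornea.
#' @param constants A [model_constants()].
#' @param method_tag Label recorded on the estimate.
#' @return A `modulus_estimate`: list with `value` (MPa), `method_tag`, and
#'   `negative_flag` (`TRUE` iff the raw value is <= 0).
#' @examples
#' coeff <- shell_coefficients(cornea_geometry(7.75, 549.9))
#' ecalc(15.06, 16.89, coeff)  # ~0.234 MPa
#' @export
ecalc <- function(iopg, iopt, test, constants = model_constants(),
                  method_tag = "ecalc") {
  test <- as_shell_coefficients(test)
  stopifnot(is.numeric(iopg), is.numeric(iopt),
            all(is.finite(iopg)), all(is.finite(iopt)))
  value <- (test$b * iopg - test$c * iopt) / constants$mmhg_per_mpa
  modulus_estimate(value, method_tag)
}

modulus_estimate <- function(value, method_tag) {
  structure(list(value = value,
                 method_tag = method_tag,
                 negative_flag = value <= 0),
            class = "modulus_estimate")
}

#' @export
print.modulus_estimate <- function(x, ...) {
  flag <- if (any(x$negative_flag)) "  [non-positive: flagged]" else ""
  cat(sprintf("E (%s) = %s MPa%s\n", x$method_tag,
              paste(sprintf("%.4f", x$value), collapse = ", "), flag))
  invisible(x)
}

#' Young's modulus from the Goldmann reading alone (Eiopg)
#'
#' Applies [ecalc()] with the calculated true pressure [ioptcalc()] in place
#' of a measured contour reading, so the modulus is estimated from curvature,
#' thickness and the Goldmann reading only (the calibration-cornea
#' assumption). Proportional to the Goldmann reading at fixed geometry.
#'
#' @inheritParams ioptcalc
#' @param constants A [model_constants()].
#' @return A `modulus_estimate` tagged `"eiopg"`.
#' @examples
#' cal <- calibration_cornea(cornea_geometry(7.75, 549.9))
#' eiopg(15.06, cal$coefficients, cal)  # ~0.278 MPa at the calibration cornea
#' @export
eiopg <- function(iopg, test, calib, constants = model_constants(),
                  variant = c("consistency", "printed")) {
  variant <- match.arg(variant)
  iopt_hat <- ioptcalc(iopg, test, calib, variant = variant)
  est <- ecalc(iopg, iopt_hat, test, constants, method_tag = "eiopg")
  est
}

#' Corneal structural stiffness
#'
#' Structural stiffness of the cornea as the thickness-modulus product
#' `k = t * E` (mm times MPa, i.e. N/mm).
#'
#' @param thickness_mm Central thickness in mm (> 0).
#' @param modulus_mpa Young's modulus in MPa, or a `modulus_estimate`.
#' @return Stiffness in N/mm.
#' @examples
#' stiffness(0.5499, 0.29)  # ~0.159 N/mm
#' @export
stiffness <- function(thickness_mm, modulus_mpa) {
  if (inherits(modulus_mpa, "modulus_estimate")) modulus_mpa <- modulus_mpa$value
  stopifnot(is.numeric(thickness_mm), is.numeric(modulus_mpa))
  if (any(thickness_mm <= 0))
    stop("`thickness_mm` must be > 0", call. = FALSE)
  thickness_mm * modulus_mpa
}

#' Predicted Goldmann reading (forward model)
#'
#' Algebraic inverse of [ecalc()]: the Goldmann reading the shell model
#' predicts for a cornea of given coefficients, modulus and true pressure,
#' \deqn{IOPG = (7500 E + C\,IOPT) / B.}
#' Round-trips with [ecalc()] to numerical precision; used by the error
#' decomposition and the synthetic-cohort forward model.
#'
#' @param true_iop True intraocular pressure, mmHg.
#' @param modulus_mpa Young's modulus, MPa (scalar or vector).
#' @param test [shell_coefficients()] of the cornea.
#' @param constants A [model_constants()].
#' @return Predicted Goldmann reading in mmHg.
#' @examples
#' coeff <- shell_coefficients(cornea_geometry(7.75, 549.9))
#' predicted_iopg(16.89, 0.234, coeff)  # ~15.06
#' @export
predicted_iopg <- function(true_iop, modulus_mpa, test,
                           constants = model_constants()) {
  test <- as_shell_coefficients(test)
  if (inherits(modulus_mpa, "modulus_estimate")) modulus_mpa <- modulus_mpa$value
  if (test$b <= 0)
    stop("degenerate model: B must be > 0", call. = FALSE)
  (constants$mmhg_per_mpa * modulus_mpa + test$c * true_iop) / test$b
}

#' Audit the algebraic parses of the shell coefficients
#'
#' The shell-coefficient expressions admit several algebraic readings that
#' differ only in where a factor of 2 or a square root sits. This harness
#' evaluates both modulus estimators at reference cohort-mean inputs under
#' every parse combination and accepts a combination only when (a) the
#' two-tonometer modulus is physiologically plausible
#' (0 < E <= `max_plausible_mpa`) and (b) the calibration-cornea
#' Goldmann-only modulus falls inside `eiopg_band`, the plausible band
#' around the modulus reported for normal young corneas (0.29 +/- 0.05 MPa).
#' Under the default parse the reference inputs give Ecalc ~ 0.234 MPa and
#' calibration Eiopg ~ 0.278 MPa; every alternative parse fails at least one
#' screen.
#'
#' @param geometry Reference geometry (default: cohort-mean cornea,
#'   R = 7.75 mm, t = 549.9 um).
#' @param iopg,iopt Reference cohort-mean pressures in mmHg.
#' @param constants A [model_constants()].
#' @param max_plausible_mpa Upper bound of the plausible two-tonometer
#'   modulus band.
#' @param eiopg_band Plausible band (MPa) for the calibration-cornea
#'   Goldmann-only modulus at the reference Goldmann reading.
#' @return A data.frame with one row per parse combination: `b_parse`,
#'   `c_parse`, `b`, `c`, `ecalc_mpa`, `eiopg_mpa`, `accepted`.
#' @examples
#' audit_parses()
#' @export
audit_parses <- function(geometry = cornea_geometry(7.75, 549.9),
                         iopg = 15.06, iopt = 16.89,
                         constants = model_constants(),
                         max_plausible_mpa = 0.5,
                         eiopg_band = c(0.24, 0.34)) {
  b_parses <- c("default", "no_sqrt", "squared_chord")
  c_parses <- c("default", "two_nu_denominator", "two_nu_numerator")
  grid <- expand.grid(b_parse = b_parses, c_parse = c_parses,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    co <- shell_coefficients(geometry, constants,
                             b_parse = grid$b_parse[i],
                             c_parse = grid$c_parse[i])
    e <- ecalc(iopg, iopt, co, constants)$value
    # at the calibration cornea ioptcalc reduces to iopg, so Eiopg is direct
    e_g <- ecalc(iopg, iopg, co, constants)$value
    data.frame(b_parse = grid$b_parse[i], c_parse = grid$c_parse[i],
               b = co$b, c = co$c, ecalc_mpa = e, eiopg_mpa = e_g,
               accepted = e > 0 & e <= max_plausible_mpa &
                 e_g >= eiopg_band[1] & e_g <= eiopg_band[2])
  })
  do.call(rbind, rows)
}
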