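#' Model constants for the thin-shell applanation model
#'
#' Fixed physical and instrument constants of the spherical-shell applanation
#' model. The defaults are the values used throughout the corneal literature
#' for Goldmann applanation on a near-incompressible cornea: Poisson's ratio
#' 0.49, an applanated area of 7.35 mm^2, and the pressure-unit divisor 7500
#' that converts the mmHg-scale coefficient products to MPa.
#'
#' @param poisson_ratio Poisson's ratio of the corneal tissue (dimensionless,
#'   in `[0, 1)`). Default 0.49 (near-incompressible).
#' @param applanation_area Applanated corneal area in mm^2. Default 7.35,
#'   the area flattened by the Goldmann probe at the measurement endpoint.
#' @param mmhg_per_mpa Unit divisor converting the coefficient-pressure
#'   products (mmHg scale) into MPa. Default 7500.
#' @param shell_factor Dimensionless multiplier in the Goldmann-reading
#'   coefficient. Default 0.6.
#' @return An object of class `model_constants`.
#' @examples
#' model_constants()
#' @export
model_constants <- function(poisson_ratio = 0.49,
                            applanation_area = 7.35,
                            mmhg_per_mpa = 7500,
                            shell_factor = 0.6) {
  stopifnot(is.numeric(poisson_ratio), length(poisson_ratio) == 1L,
            is.numeric(applanation_area), length(applanation_area) == 1L,
            is.numeric(mmhg_per_mpa), length(mmhg_per_mpa) == 1L,
            is.numeric(shell_factor), length(shell_factor) == 1L)
  if (poisson_ratio < 0 || poisson_ratio >= 1)
    stop("`poisson_ratio` must lie in [0, 1)", call. = FALSE)
  if (applanation_area <= 0)
    stop("invalid constants: `applanation_area` must be > 0", call. = FALSE)
  if (mmhg_per_mpa <= 0)
    stop("invalid constants: `mmhg_per_mpa` must be > 0", call. = FALSE)
  structure(
    list(poisson_ratio = poisson_ratio,
         applanation_area = applanation_area,
         mmhg_per_mpa = mmhg_per_mpa,
         shell_factor = shell_factor),
    class = "model_constants"
  )
}

#' @export
print.model_constants <- function(x, ...) {
  cat("Thin-shell applanation model constants\n")
  cat(sprintf("  Poisson's ratio (nu): %.3f\n", x$poisson_ratio))
  cat(sprintf("  Applanation area (A): %.3f mm^2\n", x$applanation_area))
  cat(sprintf("  mmHg per MPa divisor: %g\n", x$mmhg_per_mpa))
  cat(sprintf("  Shell factor:         %.3f\n", x$shell_factor))
  invisible(x)
}
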