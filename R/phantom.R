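#' Silicone phantom specification
#'
#' Describes the tubular silicone phantom used to validate the platform: a
#' thin-walled compliant tube (default 3.2 mm inner diameter, 0.4 mm wall,
#' matching small-caliber vascular grafts) whose inner diameter distends
#' linearly with luminal pressure.
#'
#' The distension law is linear:
#' \deqn{D_i(p) = D_{ref} (1 + \delta (p - p_{ref}))}
#' where \eqn{\delta} is the fractional diameter change per mmHg. A linear law
#' is adequate over the 40 mmHg windows used in compliance testing, where the
#' measured pressure-diameter anchors are near-linear, and it is the natural
#' counterpart of a two-point compliance characterization.
#'
#' @param inner_diameter_ref Inner diameter (mm) at `reference_pressure`.
#' @param wall_thickness Wall thickness (mm), assumed pressure-invariant.
#' @param length Sample length (mm); informational.
#' @param distension_coeff Fractional inner-diameter change per mmHg
#'   (dimensionless/mmHg, >= 0; 0 gives a rigid tube).
#' @param reference_pressure Pressure (mmHg) at which `inner_diameter_ref`
#'   holds.
#' @return An object of class `phantom_spec`.
#' @seealso [phantom_from_anchors()] to calibrate from two measured
#'   pressure-diameter pairs, [diameter_at_pressure()].
#' @export
phantom_spec <- function(inner_diameter_ref = 3.2,
                         wall_thickness = 0.4,
                         length = 40,
                         distension_coeff = 7.55e-5,
                         reference_pressure = 0) {
  stopifnot(is.numeric(inner_diameter_ref), inner_diameter_ref > 0,
            is.numeric(wall_thickness), wall_thickness > 0,
            is.numeric(distension_coeff), distension_coeff >= 0,
            is.numeric(length), length > 0)
  structure(list(
    inner_diameter_ref = inner_diameter_ref,
    wall_thickness = wall_thickness,
    length = length,
    distension_coeff = distension_coeff,
    reference_pressure = reference_pressure
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  cat(sprintf("  inner diameter: %.4f mm at %.1f mmHg\n",
              x$inner_diameter_ref, x$reference_pressure))
  cat(sprintf("  wall thickness: %.3f mm\n", x$wall_thickness))
  cat(sprintf("  distension:     %.3e /mmHg\n", x$distension_coeff))
  invisible(x)
}

#' Calibrate a phantom from two pressure-diameter anchors
#'
#' Fits the linear distension law exactly through two measured
#' (pressure, inner diameter) pairs, e.g. the per-regime mean diameters
#' reported by a bench compliance test.
#'
#' @param p1,d1 First anchor: pressure (mmHg) and inner diameter (mm).
#' @param p2,d2 Second anchor, with `p2 > p1`.
#' @param wall_thickness Wall thickness (mm).
#' @param length Sample length (mm).
#' @return A `phantom_spec` reproducing both anchors exactly.
#' @examples
#' ph <- phantom_from_anchors(79.67, 3.227, 120.72, 3.237)
#' diameter_at_pressure(ph, 79.67)$inner   # 3.227
#' @export
phantom_from_anchors <- function(p1, d1, p2, d2, wall_thickness = 0.4,
                                 length = 40) {
  stopifnot(p2 > p1, d1 > 0, d2 > 0)
  slope <- (d2 - d1) / (p2 - p1)            # mm per mmHg
  phantom_spec(inner_diameter_ref = d1,
               wall_thickness = wall_thickness,
               length = length,
               distension_coeff = slope / d1,
               reference_pressure = p1)
}

#' Construct a phantom with a prescribed dynamic radial compliance
#'
#' Chooses the distension coefficient so that the compliance equation
#' evaluated between `p_anchor` and any nearby pressure returns `c_star`
#' (in % per 1e-2 mmHg, the ISO 7198 unit) in the small-strain limit.
#'
#' @param c_star Target dynamic radial compliance, % 1e-2/mmHg.
#' @param inner_diameter_ref,wall_thickness,length,p_anchor Geometry and the
#'   pressure (mmHg) at which `inner_diameter_ref` holds.
#' @return A `phantom_spec`.
#' @export
phantom_with_compliance <- function(c_star, inner_diameter_ref = 3.2,
                                    wall_thickness = 0.4, length = 40,
                                    p_anchor = 80) {
  stopifnot(c_star >= 0)
  phantom_spec(inner_diameter_ref = inner_diameter_ref,
               wall_thickness = wall_thickness,
               length = length,
               distension_coeff = c_star * 1e-4,
               reference_pressure = p_anchor)
}

#' Phantom diameter at a given luminal pressure
#'
#' Evaluates the linear distension law. The wall is treated as
#' pressure-invariant, so outer = inner + 2 x wall thickness.
#'
#' @param spec A [phantom_spec()].
#' @param p Luminal pressure(s), mmHg (vectorized).
#' @return A list with numeric vectors `inner` and `outer` (mm).
#' @export
diameter_at_pressure <- function(spec, p) {
  stopifnot(inherits(spec, "phantom_spec"), is.numeric(p))
  inner <- spec$inner_diameter_ref *
    (1 + spec$distension_coeff * (p - spec$reference_pressure))
  if (any(inner <= 0)) {
    stop("pressure drives inner diameter <= 0; outside the linear law's range")
  }
  list(inner = inner, outer = inner + 2 * spec$wall_thickness)
}

#' Dynamic viscosity of a glycerol-water mixture
#'
#' Cheng's (2008) empirical correlation for the dynamic viscosity of
#' glycerol-water mixtures, valid for 0-100 degC and the full composition
#' range. The mixture viscosity is a composition-weighted geometric mean of
#' the pure-component viscosities:
#' \deqn{\mu = \mu_w^{\alpha} \mu_g^{1-\alpha}}
#' with a temperature- and composition-dependent exponent. Used to model the
#' 50% (w/w) glycerol working fluid that mimics blood viscosity at 37 degC.
#'
#' @param mass_fraction Glycerol mass fraction, in \[0, 1\].
#' @param temperature_C Temperature in degrees Celsius, in \[0, 100\].
#' @return Dynamic viscosity in mPa s (= cP).
#' @references Cheng, N.-S. (2008). Formula for the viscosity of a
#'   glycerol-water mixture. Industrial & Engineering Chemistry Research,
#'   47(9), 3285-3288.
#' @examples
#' glycerol_viscosity(0.5, 37)   # ~3.4 mPa s, blood-mimicking
#' glycerol_viscosity(0, 20)     # ~1.0 mPa s, pure water
#' @export
glycerol_viscosity <- function(mass_fraction, temperature_C) {
  stopifnot(is.numeric(mass_fraction), is.numeric(temperature_C))
  if (any(mass_fraction < 0 | mass_fraction > 1)) {
    stop("mass_fraction must lie in [0, 1]")
  }
  if (any(temperature_C < 0 | temperature_C > 100)) {
    stop("temperature_C outside the correlation's validity range [0, 100] degC")
  }
  T <- temperature_C
  w <- mass_fraction
  mu_w <- 1.790 * exp(-(1230 + T) * T / (36100 + 360 * T))
  mu_g <- 12100 * exp((-1233 + T) * T / (9900 + 70 * T))
  a <- 0.705 - 0.0017 * T
  b <- (4.9 + 0.036 * T) * a^2.5
  alpha <- 1 - w + a * b * w * (1 - w) / (a * w + b * (1 - w))
  mu_w^alpha * mu_g^(1 - alpha)
}

#' Poiseuille wall shear stress in a cylindrical tube
#'
#' Mean wall shear stress for fully developed laminar flow,
#' \deqn{\tau = \frac{4 \mu Q}{\pi r^3}}
#' with all quantities converted to SI internally; the result is in Pa.
#' This is the standard estimate for the hemodynamic load on the graft lumen
#' at the mean perfusion rate.
#'
#' @param flow_ml_min Volumetric flow rate, mL/min (>= 0).
#' @param viscosity_mPas Dynamic viscosity, mPa s (> 0).
#' @param lumen_diameter_mm Lumen diameter, mm (> 0).
#' @return Wall shear stress, Pa.
#' @examples
#' poiseuille_wss(188.42, 3.5, 3.2)  # ~3.4 Pa, coronary-like perfusion
#' @export
poiseuille_wss <- function(flow_ml_min, viscosity_mPas, lumen_diameter_mm) {
  stopifnot(is.numeric(flow_ml_min), is.numeric(viscosity_mPas),
            is.numeric(lumen_diameter_mm))
  if (any(flow_ml_min < 0)) stop("flow must be >= 0")
  if (any(viscosity_mPas <= 0)) stop("viscosity must be > 0")
  if (any(lumen_diameter_mm <= 0)) stop("lumen diameter must be > 0")
  q_si <- flow_ml_min * 1e-6 / 60          # m^3/s
  mu_si <- viscosity_mPas * 1e-3           # Pa s
  r_si <- lumen_diameter_mm / 2 * 1e-3     # m
  4 * mu_si * q_si / (pi * r_si^3)
}
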