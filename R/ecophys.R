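## Leaf drying-curve eco-physiology: minimum conductance, water saturation
## deficit, droplet contact angle.

MW_WATER <- 18.015   # g mol^-1
R_GAS <- 8.314       # J mol^-1 K^-1

#' Construct a leaf drying curve
#'
#' A drying curve records the mass of a detached, fully hydrated leaf at a
#' series of timepoints as it air-dries, together with the leaf's saturation
#' mass (mass at detachment), oven dry mass, projected area, and the ambient
#' conditions (temperature, relative humidity, pressure) logged at each
#' weighing. It is the raw input from which minimum conductance and water
#' saturation deficit are derived.
#'
#' @param leaf_id Character label for the leaf.
#' @param times_min Numeric vector of minutes since detachment, strictly
#'   increasing, starting at or after 0.
#' @param masses_g Leaf fresh masses (g) at `times_min`.
#' @param sm_g Saturation mass (g), the fully hydrated mass at detachment.
#' @param dm_g Oven dry mass (g).
#' @param area_m2 One-sided projected leaf area (m^2).
#' @param env Data frame with one row per timepoint and columns `temp_c`,
#'   `rh_pct`, `pressure_kpa`. A single-row data frame is recycled.
#'
#' @return An object of class `drying_curve`.
#' @export
drying_curve <- function(leaf_id, times_min, masses_g, sm_g, dm_g, area_m2,
                         env) {
  if (length(times_min) != length(masses_g))
    stop("times and masses must have equal length")
  if (length(times_min) < 2) stop("a drying curve needs >= 2 timepoints")
  if (any(diff(times_min) <= 0)) stop("times must be strictly increasing")
  if (!(sm_g > dm_g) || dm_g <= 0) stop("need SM > DM > 0")
  if (sm_g < max(masses_g) - 1e-12)
    stop("saturation mass must be >= every measured mass")
  if (dm_g > min(masses_g) + 1e-12)
    stop("dry mass must be <= every measured mass")
  if (area_m2 <= 0) stop("leaf area must be positive")
  env <- as.data.frame(env)
  needed <- c("temp_c", "rh_pct", "pressure_kpa")
  if (!all(needed %in% names(env)))
    stop("env must have columns temp_c, rh_pct, pressure_kpa")
  if (nrow(env) == 1) env <- env[rep(1L, length(times_min)), , drop = FALSE]
  if (nrow(env) != length(times_min))
    stop("env must have one row per timepoint (or a single row)")
  if (any(env$rh_pct < 0 | env$rh_pct > 100))
    stop("relative humidity must be in [0, 100]")
  if (any(env$pressure_kpa <= 0)) stop("pressure must be positive")
  if (any(env$temp_c <= -40)) stop("temperature out of range")
  rownames(env) <- NULL
  structure(
    list(leaf_id = as.character(leaf_id), times_min = as.numeric(times_min),
         masses_g = as.numeric(masses_g), sm_g = sm_g, dm_g = dm_g,
         area_m2 = area_m2, env = env),
    class = "drying_curve")
}

#' @export
print.drying_curve <- function(x, ...) {
  cat(sprintf("<drying_curve> leaf %s: %d timepoints over %g min, A = %g m^2\n",
              x$leaf_id, length(x$times_min), max(x$times_min), x$area_m2))
  invisible(x)
}

#' Interval transpiration rates from a drying curve
#'
#' The transpiration rate over each consecutive weighing interval is the mass
#' loss divided by leaf area and interval duration,
#' J = dM / (A * dt), reported in g m^-2 s^-1.
#'
#' @param curve A [drying_curve()].
#' @return Data frame with one row per interval: `t_start_min`, `t_end_min`,
#'   `flux_g_m2_s`.
#' @export
transpiration_rate <- function(curve) {
  stopifnot(inherits(curve, "drying_curve"))
  n <- length(curve$times_min)
  dt_s <- diff(curve$times_min) * 60
  dm <- -diff(curve$masses_g)
  data.frame(t_start_min = curve$times_min[-n],
             t_end_min = curve$times_min[-1],
             flux_g_m2_s = dm / (curve$area_m2 * dt_s))
}

#' Water vapour concentration of air
#'
#' Absolute humidity (g m^-3) from temperature and relative humidity, via the
#' Magnus saturation vapour pressure e_s(T) = 610.94 exp(17.625 T / (243.04 +
#' T)) Pa and the ideal gas law: c = (RH/100) e_s(T) M_w / (R (T + 273.15)).
#' Total air pressure does not enter the vapour-phase ideal-gas relation; the
#' argument is accepted for interface symmetry with the logger records and
#' used by [gmin_to_mmol()].
#'
#' @param temp_c Air temperature, degrees C.
#' @param rh_pct Relative humidity, percent in \[0, 100\].
#' @param pressure_kpa Air pressure (kPa); unused here.
#' @param magnus Numeric vector `c(a, b, c)` of Magnus constants (Pa, -, degC).
#' @return Vapour concentration in g m^-3.
#' @export
vapour_concentration <- function(temp_c, rh_pct, pressure_kpa = 101.325,
                                 magnus = c(610.94, 17.625, 243.04)) {
  if (any(rh_pct < 0 | rh_pct > 100))
    stop("relative humidity must be in [0, 100]")
  if (any(temp_c <= -40)) stop("temperature out of range")
  es <- magnus[1] * exp(magnus[2] * temp_c / (magnus[3] + temp_c))
  (rh_pct / 100) * es * MW_WATER / (R_GAS * (temp_c + 273.15))
}

#' Minimum leaf conductance from a drying curve
#'
#' After stomatal closure the transpiration of a detached leaf levels off to a
#' plateau governed by the cuticle (plus incompletely closed stomata). The
#' minimum conductance is the mean plateau flux divided by the leaf-to-air
#' vapour concentration gradient, g_min = J / dC, with dC = c_i - c_a, where
#' c_i assumes saturated air (RH 100%) inside the leaf at ambient temperature
#' and c_a is the ambient vapour concentration. All weighing intervals whose
#' start time is at or past `plateau_start_min` contribute to the plateau
#' mean, and the environment records over those timepoints are averaged.
#'
#' @param curve A [drying_curve()].
#' @param plateau_start_min Minutes of drying after which the flux is treated
#'   as the cuticular plateau (default 90).
#' @return `g_min` in m s^-1 (scalar).
#' @export
minimum_conductance <- function(curve, plateau_start_min = 90) {
  stopifnot(inherits(curve, "drying_curve"))
  if (max(curve$times_min) < plateau_start_min)
    stop("drying curve is shorter than the requested plateau start")
  fl <- transpiration_rate(curve)
  keep <- fl$t_start_min >= plateau_start_min
  if (!any(keep)) stop("no weighing interval starts within the plateau")
  j <- mean(fl$flux_g_m2_s[keep])
  idx <- curve$times_min >= plateau_start_min
  temp <- mean(curve$env$temp_c[idx])
  rh <- mean(curve$env$rh_pct[idx])
  p <- mean(curve$env$pressure_kpa[idx])
  c_i <- vapour_concentration(temp, 100, p)
  c_a <- vapour_concentration(temp, rh, p)
  dc <- c_i - c_a
  if (dc <= 0)
    stop("saturated air over the plateau (RH = 100%): vapour gradient is zero")
  j / dc
}

#' Water saturation deficit
#'
#' The percentage of water missing from a leaf relative to full saturation:
#' WSD = (SM - FM) / (SM - DM) * 100, where SM is the saturation mass, FM the
#' fresh mass at the time of interest and DM the dry mass.
#'
#' @param sm_g,fm_g,dm_g Saturation, fresh and dry mass (same units).
#' @return WSD in percent, in \[0, 100\].
#' @export
water_saturation_deficit <- function(sm_g, fm_g, dm_g) {
  if (any(sm_g <= dm_g)) stop("need SM > DM")
  if (any(fm_g > sm_g + 1e-12) || any(fm_g < dm_g - 1e-12))
    stop("need DM <= FM <= SM")
  (sm_g - fm_g) / (sm_g - dm_g) * 100
}

#' Contact angle from sessile-drop cap geometry
#'
#' Under a spherical-cap model of a sessile droplet, the contact angle at the
#' three-phase line is theta = 2 atan(2 h / w) where h is the cap height and
#' w the base (contact-line) width. Larger angles mean a less wettable
#' surface.
#'
#' @param base_width Droplet base width (any length unit).
#' @param cap_height Droplet cap height (same unit).
#' @return Contact angle in degrees, in (0, 180).
#' @export
contact_angle_from_cap <- function(base_width, cap_height) {
  if (any(base_width <= 0) || any(cap_height <= 0))
    stop("droplet geometry must be positive")
  2 * atan(2 * cap_height / base_width) * 180 / pi
}

#' Cap height for a given contact angle (inverse of the cap model)
#'
#' @param theta_deg Contact angle in degrees, in (0, 180).
#' @param base_width Droplet base width.
#' @return Cap height in the unit of `base_width`.
#' @export
cap_height_from_angle <- function(theta_deg, base_width) {
  if (any(theta_deg <= 0 | theta_deg >= 180)) stop("theta must be in (0, 180)")
  if (any(base_width <= 0)) stop("base width must be positive")
  base_width / 2 * tan(theta_deg * pi / 360)
}

#' Convert conductance from m s^-1 to mmol m^-2 s^-1
#'
#' Multiplies by the molar density of air, P / (R T), in mol m^-3, times 1000.
#'
#' @param gmin_m_s Conductance in m s^-1.
#' @param temp_c Air temperature (degrees C).
#' @param pressure_kpa Air pressure (kPa).
#' @return Conductance in mmol m^-2 s^-1.
#' @export
gmin_to_mmol <- function(gmin_m_s, temp_c = 20, pressure_kpa = 101.325) {
  gmin_m_s * (pressure_kpa * 1000) / (R_GAS * (temp_c + 273.15)) * 1000
}

#' Read drying curves from a long-format TSV
#'
#' Expected columns: `leaf_id`, `time_min`, `mass_g`, `sm_g`, `dm_g`,
#' `area_m2`, `temp_c`, `rh_pct`, `pressure_kpa`; one row per leaf and
#' timepoint.
#'
#' @param path Path to the TSV file.
#' @return Named list of [drying_curve()] objects.
#' @export
read_drying_curves <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(d, d$leaf_id), function(g) {
    g <- g[order(g$time_min), ]
    drying_curve(g$leaf_id[1], g$time_min, g$mass_g, g$sm_g[1], g$dm_g[1],
                 g$area_m2[1],
                 g[, c("temp_c", "rh_pct", "pressure_kpa")])
  })
}

#' Compute the leaf trait table from raw measurements
#'
#' Runs the full eco-physiological reduction: minimum conductance and water
#' saturation deficit (at the final weighing) from each drying curve, and
#' adaxial/abaxial contact angles from droplet geometry, joined with
#' population metadata.
#'
#' @param curves Named list of [drying_curve()] objects.
#' @param droplets Data frame with columns `leaf_id`, `side`
#'   (`"adaxial"`/`"abaxial"`), `width_mm`, `height_mm`.
#' @param metadata Data frame with columns `leaf_id`, `population`, `ecotype`,
#'   `region`, `garden`.
#' @param plateau_start_min Plateau onset passed to [minimum_conductance()].
#' @return Data frame with one row per leaf: metadata columns plus `gmin_m_s`,
#'   `wsd_pct`, `theta_adaxial`, `theta_abaxial`.
#' @export
compute_traits <- function(curves, droplets, metadata,
                           plateau_start_min = 90) {
  gmin <- vapply(curves, minimum_conductance, numeric(1),
                 plateau_start_min = plateau_start_min)
  wsd <- vapply(curves, function(cv) {
    water_saturation_deficit(cv$sm_g, cv$masses_g[length(cv$masses_g)],
                             cv$dm_g)
  }, numeric(1))
  traits <- data.frame(leaf_id = names(curves), gmin_m_s = unname(gmin),
                       wsd_pct = unname(wsd), stringsAsFactors = FALSE)
  droplets$theta <- contact_angle_from_cap(droplets$width_mm,
                                           droplets$height_mm)
  for (side in c("adaxial", "abaxial")) {
    sub <- droplets[droplets$side == side, c("leaf_id", "theta")]
    names(sub)[2] <- paste0("theta_", side)
    traits <- merge(traits, sub, by = "leaf_id", all.x = TRUE)
  }
  out <- merge(metadata, traits, by = "leaf_id")
  out[order(out$leaf_id), , drop = FALSE]
}
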