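#' Optics of the miniaturized microscope
#'
#' Describes the imaging geometry of the chamber-reading microscope: a fixed
#' field of view of 0.61 mm x 0.46 mm sampled on a regular pixel grid.  The
#' default pixel pitch of 0.476 um/px corresponds to a 1282-px-wide sensor
#' spanning the 610 um field.  `defocus_blur_coeff` is used only by the
#' synthetic renderer: an object floating `z` um above the chamber floor is
#' blurred with a Gaussian of standard deviation `defocus_blur_coeff * z` um,
#' emulating a focal plane locked to the floor.
#'
#' @param fov_x,fov_y Field of view (um).
#' @param pixel_size Pixel pitch (um per pixel).
#' @param defocus_blur_coeff Blur radius growth per unit height (um blur per
#'   um of height above the floor); simulator only.
#' @return An object of class `optics_spec`.
#' @export
#' @examples
#' optics_spec()
optics_spec <- function(fov_x = 610, fov_y = 460, pixel_size = 0.476,
                        defocus_blur_coeff = 0.02) {
  check_number(fov_x, "fov_x", min = 0, strict_min = TRUE)
  check_number(fov_y, "fov_y", min = 0, strict_min = TRUE)
  check_number(pixel_size, "pixel_size", min = 0, strict_min = TRUE)
  check_number(defocus_blur_coeff, "defocus_blur_coeff", min = 0)
  width <- as.integer(round(fov_x / pixel_size))
  height <- as.integer(round(fov_y / pixel_size))
  if (width < 64L) {
    abort_validation("`fov_x` / `pixel_size` must give an image at least 64 px wide",
                     "pixel_size")
  }
  structure(
    list(fov_x = fov_x, fov_y = fov_y, pixel_size = pixel_size,
         defocus_blur_coeff = defocus_blur_coeff,
         width_px = width, height_px = height),
    class = "optics_spec"
  )
}

#' Counting-chamber geometry
#'
#' The counting chamber is a hemocytometer-style well whose height (532 um by
#' default, about five times a standard hemocytometer) sets both the control
#' volume and the sedimentation wait.  Concentrations are computed over
#' `analysis_volume`, the total volume corresponding to the `n_areas` imaged
#' areas; the default 588 nL is the instrument's calibrated value and is kept
#' as an independent constant rather than recomputed from the field of view
#' (see the methods vignette).
#'
#' @param h_c Chamber height (um).
#' @param n_areas Number of imaged areas per chamber.
#' @param analysis_volume Total analyzed volume across areas (nL).
#' @return An object of class `chamber_spec`.
#' @export
chamber_spec <- function(h_c = 532, n_areas = 4, analysis_volume = 588) {
  check_number(h_c, "h_c", min = 0, strict_min = TRUE)
  check_number(n_areas, "n_areas", min = 1)
  check_number(analysis_volume, "analysis_volume", min = 0, strict_min = TRUE)
  structure(
    list(h_c = h_c, n_areas = as.integer(n_areas),
         analysis_volume = analysis_volume),
    class = "chamber_spec"
  )
}

#' Circle-detection parameters
#'
#' Gates for the circle Hough detector.  `sensitivity_threshold` is the
#' minimum normalized accumulator score (a radial-symmetry measure in
#' \[0, 1\]) an object must reach: raising it rejects progressively less
#' circular objects.  The diameter band \[`d_min`, `d_max`\] (8.6-14.2 um by
#' default) passes single blood cells while excluding sub-cellular debris and
#' oversized clumps.
#'
#' @param sensitivity_threshold Minimum normalized accumulator score in
#'   \[0, 1\].
#' @param d_min,d_max Lower/upper apparent-diameter cut-off (um).
#' @param radius_step Accumulator radius discretization (um).
#' @param min_center_distance Non-maximum-suppression radius (um); defaults to
#'   `d_min`, since two true cells closer than one small-cell diameter are
#'   optically merged anyway.
#' @param edge_percentile Fraction of gradient magnitudes kept out of the edge
#'   mask; pixels above this percentile of nonzero magnitudes vote.
#' @param gradient_ref_bf,gradient_ref_fl Reference gradient magnitude
#'   (intensity units per pixel) of a nominal in-focus object edge in each
#'   channel; Hough votes are weighted by `magnitude / reference`.  The
#'   instrument has fixed illumination and camera gain, so a calibrated
#'   per-channel constant is the stable choice; set to `NULL` to estimate
#'   the reference from the frame itself (uncalibrated images; less robust
#'   when a frame holds very few or very many objects).
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(sensitivity_threshold = 0.9, d_min = 8.6,
                             d_max = 14.2, radius_step = 0.5,
                             min_center_distance = d_min,
                             edge_percentile = 0.95,
                             gradient_ref_bf = 3200,
                             gradient_ref_fl = 235) {
  check_number(sensitivity_threshold, "sensitivity_threshold", min = 0, max = 1)
  check_number(d_min, "d_min", min = 0, strict_min = TRUE)
  check_number(d_max, "d_max", min = 0, strict_min = TRUE)
  if (d_min >= d_max) {
    abort_validation(sprintf(
      "diameter band invalid: `d_min` (%g) must be < `d_max` (%g)", d_min, d_max
    ), "d_min")
  }
  check_number(radius_step, "radius_step", min = 0, strict_min = TRUE)
  check_number(min_center_distance, "min_center_distance", min = 0)
  check_number(edge_percentile, "edge_percentile", min = 0, max = 1)
  check_number(gradient_ref_bf, "gradient_ref_bf", min = 0,
               strict_min = TRUE, allow_null = TRUE)
  check_number(gradient_ref_fl, "gradient_ref_fl", min = 0,
               strict_min = TRUE, allow_null = TRUE)
  structure(
    list(sensitivity_threshold = sensitivity_threshold, d_min = d_min,
         d_max = d_max, radius_step = radius_step,
         min_center_distance = min_center_distance,
         edge_percentile = edge_percentile,
         gradient_ref_bf = gradient_ref_bf, gradient_ref_fl = gradient_ref_fl),
    class = "detection_params"
  )
}

#' Sedimentation parameters
#'
#' Physical parameters for gravitational settling of blood cells in the
#' chamber medium: cell volume `V_c` (um^3), cell and medium densities
#' (g/mL), medium viscosity (cP), and gravity.  When `v_override` is set
#' (default 0.92 um/s, the instrument's published red-cell settling velocity)
#' it is used for wait-time planning instead of the first-principles Stokes
#' value; see [settling_velocity()] and the methods vignette for why both are
#' carried.
#'
#' @param V_c Cell volume (um^3).
#' @param rho_c Cell density (g/mL).
#' @param rho_m Medium density (g/mL).
#' @param mu_m Medium dynamic viscosity (cP).
#' @param g Gravitational acceleration (m/s^2).
#' @param v_override Optional settling velocity (um/s) used verbatim when not
#'   `NULL`.
#' @return An object of class `sedimentation_params`.
#' @export
sedimentation_params <- function(V_c = 90, rho_c = 1.09, rho_m = 1.04,
                                 mu_m = 1.05, g = 9.81, v_override = 0.92) {
  check_number(V_c, "V_c", min = 0, strict_min = TRUE)
  check_number(rho_c, "rho_c", min = 0, strict_min = TRUE)
  check_number(rho_m, "rho_m", min = 0, strict_min = TRUE)
  check_number(mu_m, "mu_m", min = 0, strict_min = TRUE)
  check_number(g, "g", min = 0, strict_min = TRUE)
  check_number(v_override, "v_override", allow_null = TRUE)
  structure(
    list(V_c = V_c, rho_c = rho_c, rho_m = rho_m, mu_m = mu_m, g = g,
         v_override = v_override),
    class = "sedimentation_params"
  )
}

#' A staining condition
#'
#' One point in the on-chip staining protocol space: stock dye concentration
#' `c_d` (uM of nuclear stain deposited in the chamber) and incubation time
#' `t_i` (minutes between sample loading and fluorescence imaging).
#'
#' @param c_d Dye stock concentration (uM).
#' @param t_i Incubation time (min).
#' @return An object of class `staining_condition`.
#' @export
staining_condition <- function(c_d = 750, t_i = 10) {
  check_number(c_d, "c_d", min = 0)
  check_number(t_i, "t_i", min = 0)
  structure(list(c_d = c_d, t_i = t_i), class = "staining_condition")
}

#' Staining response model (simulator)
#'
#' Parametric model of how stained-cell fluorescence and background depend on
#' the staining condition, used by the synthetic renderer: cell amplitude
#' follows a Hill curve in dye concentration (half-saturation `k_half`,
#' coefficient `hill_n`) times a saturating exponential in incubation time
#' (time constant `tau`), while background grows linearly with dye
#' concentration.  Intensities are arbitrary camera units; only ratios
#' (signal-to-noise) are meaningful.  Defaults place the signal-to-noise
#' optimum at 750 uM, bring the signal within 5% of plateau at 10 min, and
#' keep the measured SNR near 6 already at 2 min incubation.
#'
#' @param s_max Peak cell fluorescence amplitude (intensity units).
#' @param k_half Half-saturation dye concentration (uM).
#' @param hill_n Hill coefficient (>= 1).
#' @param bg_slope Background intensity per uM of dye.
#' @param tau Staining time constant (min).
#' @param bg_floor Dye-independent background level.
#' @return An object of class `staining_model_params`.
#' @export
staining_model_params <- function(s_max = 3000, k_half = 750, hill_n = 2,
                                  bg_slope = 0.15, tau = 10 / 3,
                                  bg_floor = 0) {
  check_number(s_max, "s_max", min = 0, strict_min = TRUE)
  check_number(k_half, "k_half", min = 0, strict_min = TRUE)
  check_number(hill_n, "hill_n", min = 1)
  check_number(bg_slope, "bg_slope", min = 0)
  check_number(tau, "tau", min = 0, strict_min = TRUE)
  check_number(bg_floor, "bg_floor", min = 0)
  structure(
    list(s_max = s_max, k_half = k_half, hill_n = hill_n,
         bg_slope = bg_slope, tau = tau, bg_floor = bg_floor),
    class = "staining_model_params"
  )
}

#' Synthetic-scene nuisance parameters
#'
#' Rates and noise levels for the parts of the optical scene that are not
#' cells: sub-threshold debris, oversized clumps, and per-channel additive
#' camera noise.  Apparent-diameter ranges are in um; cells span 9-14 um
#' (inside the 8.6-14.2 um detection band), debris 3-7 um, clumps 16-30 um.
#'
#' @param debris_rate,clump_rate Nuisance object loads (objects/uL).
#' @param noise_sd_bf,noise_sd_fl Additive Gaussian noise standard deviation
#'   (intensity units) for the bright-field and fluorescence channels.
#' @param cell_diameter_range,debris_diameter_range,clump_diameter_range
#'   Uniform sampling ranges for apparent diameters (um).
#' @return An object of class `simulator_params`.
#' @export
simulator_params <- function(debris_rate = 20, clump_rate = 5,
                             noise_sd_bf = 300, noise_sd_fl = 8,
                             cell_diameter_range = c(9, 14),
                             debris_diameter_range = c(3, 7),
                             clump_diameter_range = c(16, 30)) {
  check_number(debris_rate, "debris_rate", min = 0)
  check_number(clump_rate, "clump_rate", min = 0)
  check_number(noise_sd_bf, "noise_sd_bf", min = 0)
  check_number(noise_sd_fl, "noise_sd_fl", min = 0)
  structure(
    list(debris_rate = debris_rate, clump_rate = clump_rate,
         noise_sd_bf = noise_sd_bf, noise_sd_fl = noise_sd_fl,
         cell_diameter_range = cell_diameter_range,
         debris_diameter_range = debris_diameter_range,
         clump_diameter_range = clump_diameter_range),
    class = "simulator_params"
  )
}

#' Default full configuration
#'
#' Bundles optics, chamber, detection, sedimentation, staining, and simulator
#' parameters at their instrument defaults.  All pipeline entry points accept
#' such a configuration.
#'
#' @param ... Named components to replace, e.g.
#'   `default_config(chamber = chamber_spec(h_c = 337))`.
#' @return An object of class `csf_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$chamber$h_c
default_config <- function(...) {
  cfg <- structure(
    list(optics = optics_spec(), chamber = chamber_spec(),
         detection = detection_params(),
         sedimentation = sedimentation_params(),
         staining_model = staining_model_params(),
         staining = staining_condition(),
         simulator = simulator_params()),
    class = "csf_config"
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) {
      abort_validation(sprintf("unknown configuration component `%s`", nm), nm)
    }
    cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

# Flat key -> (component, constructor argument) map for the config file.
config_key_map <- function() {
  list(
    optics = c("fov_x", "fov_y", "pixel_size", "defocus_blur_coeff"),
    chamber = c("h_c", "n_areas", "analysis_volume"),
    detection = c("sensitivity_threshold", "d_min", "d_max", "radius_step",
                  "min_center_distance", "edge_percentile",
                  "gradient_ref_bf", "gradient_ref_fl"),
    sedimentation = c("V_c", "rho_c", "rho_m", "mu_m", "g", "v_override"),
    staining_model = c("s_max", "k_half", "hill_n", "bg_slope", "tau",
                       "bg_floor"),
    staining = c("c_d", "t_i"),
    simulator = c("debris_rate", "clump_rate", "noise_sd_bf", "noise_sd_fl")
  )
}

#' Load a configuration file
#'
#' Reads a flat key-value configuration document (YAML syntax, `#` comments
#' allowed).  Every key matches a constructor argument of one of the
#' component specs ([optics_spec()], [chamber_spec()], [detection_params()],
#' [sedimentation_params()], [staining_model_params()],
#' [staining_condition()], [simulator_params()]); unspecified keys take the
#' defaults.  All invariants are validated and violations raise an error
#' naming the offending field.
#'
#' When a file states `analysis_volume` together with chamber/optics geometry
#' that implies a different volume (beyond 1%), a warning reports the
#' discrepancy and the stated `analysis_volume` wins.
#'
#' @param path Path to the configuration file.
#' @param overrides Optional named list of keys taking precedence over the
#'   file (used by the command-line interface for per-flag overrides).
#' @return A `csf_config` object.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort_input(sprintf("configuration file not found: %s", path))
    }
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
    if (!is.list(vals) || (length(vals) && is.null(names(vals)))) {
      abort_input("configuration file must contain flat `key: value` entries")
    }
  }
  vals[names(overrides)] <- overrides
  km <- config_key_map()
  known <- unlist(km, use.names = FALSE)
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    abort_validation(sprintf("unknown configuration key(s): %s",
                             paste(unknown, collapse = ", ")),
                     unknown[1])
  }
  ctors <- list(optics = optics_spec, chamber = chamber_spec,
                detection = detection_params,
                sedimentation = sedimentation_params,
                staining_model = staining_model_params,
                staining = staining_condition, simulator = simulator_params)
  cfg <- list()
  for (comp in names(km)) {
    args <- vals[intersect(names(vals), km[[comp]])]
    cfg[[comp]] <- do.call(ctors[[comp]], args)
  }
  cfg <- structure(cfg, class = "csf_config")

  if ("analysis_volume" %in% names(vals) &&
      any(c("fov_x", "fov_y", "h_c", "n_areas") %in% names(vals))) {
    geom_nl <- cfg$optics$fov_x * cfg$optics$fov_y * cfg$chamber$h_c *
      cfg$chamber$n_areas * 1e-6   # um^3 -> nL
    if (abs(geom_nl - cfg$chamber$analysis_volume) >
        0.01 * cfg$chamber$analysis_volume) {
      warn(sprintf(
        paste0("analysis_volume (%g nL) differs from the volume implied by ",
               "FOV x h_c x n_areas (%.1f nL); using the stated value"),
        cfg$chamber$analysis_volume, geom_nl
      ))
    }
  }
  cfg
}

#' Write a resolved configuration
#'
#' Serializes every tunable field of a configuration to a flat YAML document
#' that [load_config()] reads back to identical values.
#'
#' @param config A `csf_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "csf_config"))
  km <- config_key_map()
  out <- list()
  for (comp in names(km)) {
    for (key in km[[comp]]) {
      val <- config[[comp]][[key]]
      if (!is.null(val)) out[[key]] <- val
    }
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.csf_config <- function(x, ...) {
  cat("<csf_config>\n")
  cat(sprintf("  optics:    %g x %g um FOV, %g um/px (%d x %d px)\n",
              x$optics$fov_x, x$optics$fov_y, x$optics$pixel_size,
              x$optics$width_px, x$optics$height_px))
  cat(sprintf("  chamber:   h_c = %g um, %d areas, %g nL analyzed\n",
              x$chamber$h_c, x$chamber$n_areas, x$chamber$analysis_volume))
  cat(sprintf("  detection: score >= %g, diameters %g-%g um\n",
              x$detection$sensitivity_threshold, x$detection$d_min,
              x$detection$d_max))
  cat(sprintf("  staining:  c_d = %g uM, t_i = %g min\n",
              x$staining$c_d, x$staining$t_i))
  invisible(x)
}
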