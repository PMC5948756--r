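# Gravitational settling of blood cells in the counting chamber.
#
# The chamber is much taller than the microscope's depth of focus, so cells
# must settle onto the floor before they can be imaged in focus.  For dilute
# suspensions each cell falls independently at its Stokes terminal velocity;
# with initial heights uniform in [0, h_c] the settled fraction grows
# linearly in time until complete sedimentation at t_s = h_c / v.

#' Stokes settling velocity from first principles
#'
#' Terminal velocity of the volume-equivalent sphere,
#' `v = 2 (rho_c - rho_m) g r^2 / (9 mu_m)` with `r = (3 V_c / 4 pi)^(1/3)`.
#' Inputs are converted to SI internally (g/mL to kg/m^3, cP to Pa s) and the
#' result is returned in um/s.  A non-positive density contrast gives a
#' non-positive velocity and a flotation warning.
#'
#' Note: with the default red-cell parameters (`V_c` = 90 um^3,
#' density contrast 0.05 g/mL, `mu_m` = 1.05 cP) this evaluates to about
#' 0.80 um/s, whereas the instrument's published value is 0.92 um/s;
#' [settling_velocity()] therefore honours `v_override` for planning and
#' keeps this derivation available alongside.  See the methods vignette.
#'
#' @param p A [sedimentation_params()] object.
#' @return Settling velocity (um/s).
#' @export
#' @examples
#' stokes_velocity(sedimentation_params())   # ~0.80 um/s
stokes_velocity <- function(p) {
  stopifnot(inherits(p, "sedimentation_params"))
  r_m <- (3 * p$V_c / (4 * pi))^(1 / 3) * 1e-6       # um -> m
  drho <- (p$rho_c - p$rho_m) * 1000                 # g/mL -> kg/m^3
  mu <- p$mu_m * 1e-3                                # cP -> Pa s
  v_ms <- 2 * drho * p$g * r_m^2 / (9 * mu)
  v <- v_ms * 1e6                                    # m/s -> um/s
  if (v <= 0) {
    warn(sprintf("density contrast is non-positive (%g g/mL): cells float, v = %g um/s",
                 p$rho_c - p$rho_m, v))
  }
  v
}

#' Settling velocity used for planning
#'
#' Returns `p$v_override` when set, otherwise the first-principles
#' [stokes_velocity()].  The computed Stokes value is always attached as
#' attribute `"stokes"` so reports can show both.
#'
#' @param p A [sedimentation_params()] object.
#' @return Settling velocity (um/s) with attribute `stokes`.
#' @export
#' @examples
#' settling_velocity(sedimentation_params())                      # 0.92
#' settling_velocity(sedimentation_params(v_override = NULL))     # ~0.80
settling_velocity <- function(p) {
  stopifnot(inherits(p, "sedimentation_params"))
  vs <- stokes_velocity(p)
  v <- p$v_override %||% vs
  structure(v, stokes = vs)
}

#' Complete-sedimentation time
#'
#' Time for the highest-starting cell to reach the chamber floor,
#' `t_s = h_c / v`.
#'
#' @param h_c Chamber height (um).
#' @param v Settling velocity (um/s).
#' @return Time in seconds.
#' @export
#' @examples
#' sedimentation_time(532, 0.92) / 60   # ~9.6 min
sedimentation_time <- function(h_c, v) {
  check_number(h_c, "h_c", min = 0, strict_min = TRUE)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
    abort("settling velocity must be > 0 for sedimentation (cells do not settle)",
          class = "csfcount_no_sedimentation_error")
  }
  h_c / v
}

#' Fraction of cells settled by time t
#'
#' For cells with initial heights uniform in `[0, h_c]` falling at constant
#' velocity `v`, the fraction on the floor at time `t` is
#' `min(1, v t / h_c)`: arrivals are linear in time until `t_s`.
#'
#' @param t Time since loading (s); vectorized.
#' @inheritParams sedimentation_time
#' @return Settled fraction(s) in \[0, 1\].
#' @export
settled_fraction <- function(t, h_c, v) {
  check_number(h_c, "h_c", min = 0, strict_min = TRUE)
  check_number(v, "v", min = 0, strict_min = TRUE)
  if (any(t < 0)) abort_validation("`t` must be >= 0", "t")
  pmin(1, v * t / h_c)
}

#' Sedimentation summary for a chamber
#'
#' Combines velocity, complete-sedimentation time and the settling curve for
#' one chamber design into a result that can be tidied and plotted.
#'
#' @param chamber A [chamber_spec()].
#' @param p A [sedimentation_params()].
#' @return An object of class `sedimentation_result` with elements `v`
#'   (um/s, attribute `stokes` carries the first-principles value), `t_s_s`,
#'   `t_s_min`, `h_c`, and `settled_fraction(t)` (a function of seconds).
#' @export
#' @examples
#' sedimentation_result(chamber_spec(h_c = 337), sedimentation_params())
sedimentation_result <- function(chamber = chamber_spec(),
                                 p = sedimentation_params()) {
  stopifnot(inherits(chamber, "chamber_spec"))
  v <- settling_velocity(p)
  t_s <- sedimentation_time(chamber$h_c, as.numeric(v))
  h_c <- chamber$h_c
  vn <- as.numeric(v)
  structure(
    list(v = v, t_s_s = t_s, t_s_min = t_s / 60, h_c = h_c,
         settled_fraction = function(t) settled_fraction(t, h_c, vn)),
    class = "sedimentation_result"
  )
}

#' @export
print.sedimentation_result <- function(x, ...) {
  cat(sprintf("<sedimentation_result> h_c = %g um, v = %g um/s (Stokes %.3g), t_s = %.1f s = %.1f min\n",
              x$h_c, as.numeric(x$v), attr(x$v, "stokes"), x$t_s_s, x$t_s_min))
  invisible(x)
}

#' @export
tidy.sedimentation_result <- function(x, ...) {
  tibble(h_c_um = x$h_c, v_um_s = as.numeric(x$v),
         v_stokes_um_s = attr(x$v, "stokes"),
         t_s_s = x$t_s_s, t_s_min = x$t_s_min)
}

#' Recommended wait before imaging
#'
#' The protocol images once both staining and sedimentation are complete, so
#' the recommended wait is `max(t_s, t_i)` in minutes.  With the default
#' chamber (532 um, t_s = 9.6 min) and staining incubation of 10 min, the
#' staining step dominates and the wait is 10 min.
#'
#' @param chamber A [chamber_spec()].
#' @param p A [sedimentation_params()].
#' @param staining A [staining_condition()] supplying the incubation time.
#' @return Recommended wait in minutes.
#' @export
#' @examples
#' plan_wait_time(chamber_spec(), sedimentation_params(), staining_condition())
plan_wait_time <- function(chamber = chamber_spec(),
                           p = sedimentation_params(),
                           staining = staining_condition()) {
  res <- sedimentation_result(chamber, p)
  max(res$t_s_min, staining$t_i)
}

#' @export
autoplot.sedimentation_result <- function(object, ...) {
  t <- seq(0, 1.2 * object$t_s_s, length.out = 200)
  df <- tibble(t_min = t / 60, settled = object$settled_fraction(t))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min, y = .data$settled)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$t_s_min, linetype = "dashed") +
    ggplot2::labs(x = "time after loading (min)", y = "settled fraction",
                  title = sprintf("Settling in a %g um chamber (t_s = %.1f min)",
                                  object$h_c, object$t_s_min)) +
    ggplot2::theme_minimal()
}
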