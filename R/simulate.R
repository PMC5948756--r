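# Ground-truthed synthetic microscopy of the counting chamber.
#
# The simulator emulates the optical scene the detector faces: dark ring-like
# cells on a bright, textured bright-field background crossed by the faint
# grid/shadow pattern that 3D-printed chambers leave; bright nuclear-stain
# spots for WBCs only, on a dye-concentration-dependent fluorescence
# background; sub-threshold debris and oversized multi-lobed clumps; and
# height-dependent defocus blur for cells that have not yet settled onto the
# chamber floor (the focal plane).

#' Construct a ground-truth sample
#'
#' Wraps an explicit object table into the simulator's ground-truth
#' container.  Most users will call [sample_scene()] instead; this
#' constructor exists for scripted scenes (tests, worked examples) where
#' object positions are chosen by hand.
#'
#' @param objects A data frame with columns `x_um`, `y_um`, `z_um`, `class`
#'   (one of `"RBC"`, `"WBC"`, `"debris"`, `"clump"`), `diameter_um`
#'   (apparent diameter).
#' @param c_rbc,c_wbc True concentrations (cells/uL) the scene represents.
#' @param optics An [optics_spec()].
#' @param chamber A [chamber_spec()].
#' @param seed Integer seed recorded for provenance (may be `NA`).
#' @return An object of class `ground_truth_sample`.
#' @export
ground_truth_sample <- function(objects, c_rbc = NA_real_, c_wbc = NA_real_,
                                optics = optics_spec(),
                                chamber = chamber_spec(), seed = NA_integer_) {
  objects <- as_tibble(objects)
  needed <- c("x_um", "y_um", "z_um", "class", "diameter_um")
  missing_cols <- setdiff(needed, names(objects))
  if (length(missing_cols)) {
    abort_validation(sprintf("`objects` lacks column(s): %s",
                             paste(missing_cols, collapse = ", ")), "objects")
  }
  bad_class <- setdiff(unique(objects$class),
                       c("RBC", "WBC", "debris", "clump"))
  if (length(bad_class)) {
    abort_validation(sprintf("unknown object class(es): %s",
                             paste(bad_class, collapse = ", ")), "class")
  }
  if (nrow(objects)) {
    if (any(objects$x_um < 0 | objects$x_um > optics$fov_x) ||
        any(objects$y_um < 0 | objects$y_um > optics$fov_y)) {
      abort_validation("object positions must lie within the field of view", "objects")
    }
    if (any(objects$z_um < 0 | objects$z_um > chamber$h_c)) {
      abort_validation("object heights must lie within [0, h_c]", "objects")
    }
  }
  structure(
    list(objects = objects,
         true_concentrations = c(c_rbc = c_rbc, c_wbc = c_wbc),
         optics = optics, chamber = chamber, seed = seed),
    class = "ground_truth_sample"
  )
}

#' @export
print.ground_truth_sample <- function(x, ...) {
  tab <- table(factor(x$objects$class,
                      levels = c("RBC", "WBC", "debris", "clump")))
  cat(sprintf("<ground_truth_sample> %d objects (%s); c_rbc = %s, c_wbc = %s cells/uL\n",
              nrow(x$objects),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              format(x$true_concentrations[["c_rbc"]]),
              format(x$true_concentrations[["c_wbc"]])))
  invisible(x)
}

# Volume imaged by one frame (uL): FOV footprint times chamber height.
frame_volume_uL <- function(optics, chamber) {
  optics$fov_x * optics$fov_y * chamber$h_c / 1e9
}

#' Sample a random chamber scene
#'
#' Draws the objects present in one imaged area.  Counts per class are
#' Poisson with mean `concentration x frame volume` (the frame volume is the
#' field-of-view footprint times the chamber height, ~0.149 uL at defaults);
#' positions are uniform in the field, initial heights uniform in
#' `[0, h_c]`, and apparent diameters uniform within each class's range.
#'
#' @param c_rbc,c_wbc True cell concentrations (cells/uL).
#' @param optics An [optics_spec()].
#' @param chamber A [chamber_spec()].
#' @param debris_rate,clump_rate Nuisance-object loads (objects/uL).
#' @param sim A [simulator_params()] supplying diameter ranges.
#' @param seed Integer seed; identical seed and parameters give an identical
#'   sample.  `NULL` uses (and advances) the current RNG state.
#' @return A `ground_truth_sample`.
#' @export
#' @examples
#' s <- sample_scene(c_rbc = 100, c_wbc = 50, seed = 1)
#' nrow(s$objects)
sample_scene <- function(c_rbc, c_wbc, optics = optics_spec(),
                         chamber = chamber_spec(),
                         debris_rate = simulator_params()$debris_rate,
                         clump_rate = simulator_params()$clump_rate,
                         sim = simulator_params(), seed = NULL) {
  check_number(c_rbc, "c_rbc", min = 0)
  check_number(c_wbc, "c_wbc", min = 0)
  check_number(debris_rate, "debris_rate", min = 0)
  check_number(clump_rate, "clump_rate", min = 0)
  vol <- frame_volume_uL(optics, chamber)
  with_seed_if(seed, {
    counts <- c(RBC = rpois(1, c_rbc * vol), WBC = rpois(1, c_wbc * vol),
                debris = rpois(1, debris_rate * vol),
                clump = rpois(1, clump_rate * vol))
    ranges <- list(RBC = sim$cell_diameter_range,
                   WBC = sim$cell_diameter_range,
                   debris = sim$debris_diameter_range,
                   clump = sim$clump_diameter_range)
    objects <- purrr::map2(names(counts), counts, function(cls, n) {
      tibble(
        x_um = runif(n, 0, optics$fov_x),
        y_um = runif(n, 0, optics$fov_y),
        z_um = runif(n, 0, chamber$h_c),
        class = rep(cls, n),
        diameter_um = runif(n, ranges[[cls]][1], ranges[[cls]][2])
      )
    }) |> purrr::list_rbind()
    ground_truth_sample(objects, c_rbc = c_rbc, c_wbc = c_wbc,
                        optics = optics, chamber = chamber,
                        seed = seed %||% NA_integer_)
  })
}

#' Scripted scene with controlled composition and separation
#'
#' Builds a fully settled scene with exact object counts per class, positions
#' drawn uniformly but rejection-sampled so that objects neither overlap
#' (pairwise clearance `gap` beyond touching) nor cross the field border.
#' Used for benchmark suites that isolate one property (e.g. the
#' size/symmetry gate) from optical merging and border clipping;
#' [sample_scene()] remains the faithful random-loading model.
#'
#' @param n_rbc,n_wbc,n_debris,n_clump Exact object counts.
#' @param optics An [optics_spec()].
#' @param chamber A [chamber_spec()].
#' @param sim A [simulator_params()] supplying diameter ranges.
#' @param gap Minimum clearance between object boundaries (um).
#' @param seed Integer seed.
#' @return A `ground_truth_sample` with all objects on the chamber floor.
#' @export
scripted_scene <- function(n_rbc = 5, n_wbc = 0, n_debris = 10, n_clump = 2,
                           optics = optics_spec(), chamber = chamber_spec(),
                           sim = simulator_params(), gap = 5, seed = NULL) {
  with_seed_if(seed, {
    cls <- c(rep("RBC", n_rbc), rep("WBC", n_wbc),
             rep("debris", n_debris), rep("clump", n_clump))
    ranges <- list(RBC = sim$cell_diameter_range,
                   WBC = sim$cell_diameter_range,
                   debris = sim$debris_diameter_range,
                   clump = sim$clump_diameter_range)
    diam <- vapply(cls, function(cl) runif(1, ranges[[cl]][1], ranges[[cl]][2]),
                   numeric(1))
    n <- length(cls)
    xs <- ys <- numeric(n)
    for (i in seq_len(n)) {
      margin <- diam[i] / 2 + 2
      for (try in 1:500) {
        x <- runif(1, margin, optics$fov_x - margin)
        y <- runif(1, margin, optics$fov_y - margin)
        ok <- if (i == 1) TRUE else {
          all(sqrt((x - xs[seq_len(i - 1)])^2 + (y - ys[seq_len(i - 1)])^2) >=
                (diam[i] + diam[seq_len(i - 1)]) / 2 + gap)
        }
        if (ok) break
      }
      if (!ok) abort_validation("could not place objects with the requested clearance", "gap")
      xs[i] <- x; ys[i] <- y
    }
    ground_truth_sample(
      tibble(x_um = xs, y_um = ys, z_um = 0, class = cls, diameter_um = unname(diam)),
      optics = optics, chamber = chamber, seed = seed %||% NA_integer_
    )
  })
}

#' Advance sedimentation of a scene
#'
#' Lowers every object by `v * t`, clamping at the chamber floor.  Object
#' order, classes, and lateral positions are unchanged.
#'
#' @param sample A `ground_truth_sample`.
#' @param t Elapsed time (s).
#' @param v Settling velocity (um/s).
#' @return The sample with updated heights.
#' @export
settle <- function(sample, t, v) {
  stopifnot(inherits(sample, "ground_truth_sample"))
  check_number(t, "t", min = 0)
  check_number(v, "v", min = 0, strict_min = TRUE)
  sample$objects$z_um <- pmax(0, sample$objects$z_um - v * t)
  sample
}

#' Stained-cell fluorescence amplitude
#'
#' The simulator's staining response: a Hill curve in dye concentration
#' times a saturating exponential in incubation time,
#' `s_max * c_d^n / (k_half^n + c_d^n) * (1 - exp(-t_i / tau))`.
#' Monotone nondecreasing in both arguments; saturates at `s_max`.
#'
#' @param c_d Dye concentration (uM); vectorized.
#' @param t_i Incubation time (min); vectorized.
#' @param model A [staining_model_params()].
#' @return Cell fluorescence amplitude (intensity units).
#' @export
#' @examples
#' staining_signal(750, 10, staining_model_params()) # ~0.476 * s_max
staining_signal <- function(c_d, t_i, model = staining_model_params()) {
  stopifnot(inherits(model, "staining_model_params"))
  if (any(c_d < 0)) abort_validation("`c_d` must be >= 0", "c_d")
  if (any(t_i < 0)) abort_validation("`t_i` must be >= 0", "t_i")
  hill <- ifelse(c_d == 0 & model$k_half == 0, 0,
                 c_d^model$hill_n / (model$k_half^model$hill_n + c_d^model$hill_n))
  model$s_max * hill * (1 - exp(-t_i / model$tau))
}

# Background fluorescence level for a staining condition.
fluorescence_background <- function(c_d, model) {
  model$bg_floor + model$bg_slope * c_d
}

# Smooth random field: bilinear upsampling of coarse white noise; used for
# the mottled bright-field background.  `scale` is the correlation length in
# pixels.  Draws from the current RNG.
smooth_field <- function(H, W, scale) {
  hc <- ceiling(H / scale) + 2L
  wc <- ceiling(W / scale) + 2L
  cm <- matrix(rnorm(hc * wc), hc, wc)
  ry <- (seq_len(H) - 1) / scale + 1
  rx <- (seq_len(W) - 1) / scale + 1
  y0 <- pmin(floor(ry), hc - 1L); x0 <- pmin(floor(rx), wc - 1L)
  fy <- ry - y0; fx <- rx - x0
  A <- cm[y0, x0, drop = FALSE]; B <- cm[y0 + 1, x0, drop = FALSE]
  C <- cm[y0, x0 + 1, drop = FALSE]; D <- cm[y0 + 1, x0 + 1, drop = FALSE]
  FY <- matrix(fy, H, W); FX <- matrix(fx, H, W, byrow = TRUE)
  (1 - FY) * (1 - FX) * A + FY * (1 - FX) * B + (1 - FY) * FX * C + FY * FX * D
}

# Faint periodic grid shadow from 3D-printing layers: Gaussian dark lines in
# both directions with the given period (px) and line width (px).
grid_pattern <- function(H, W, period, width) {
  line_profile <- function(n) {
    u <- ((seq_len(n) - 1) + period / 2) %% period - period / 2
    exp(-0.5 * (u / width)^2)
  }
  outer(line_profile(H), rep(1, W)) + outer(rep(1, H), line_profile(W))
}

# Composite one object's contribution into the canvas (side effect free:
# returns the patch and its index ranges).  `profile_fn(d_um, theta)` maps
# distance-from-centre (um) and polar angle to intensity contribution.
object_patch <- function(canvas_dim, cx_px, cy_px, extent_px, pixel_size,
                         profile_fn) {
  H <- canvas_dim[1]; W <- canvas_dim[2]
  i0 <- max(1L, floor(cy_px - extent_px)); i1 <- min(H, ceiling(cy_px + extent_px))
  j0 <- max(1L, floor(cx_px - extent_px)); j1 <- min(W, ceiling(cx_px + extent_px))
  if (i0 > i1 || j0 > j1) return(NULL)
  dy <- (i0:i1) - cy_px
  dx <- (j0:j1) - cx_px
  DY <- matrix(dy, length(dy), length(dx))
  DX <- matrix(dx, length(dy), length(dx), byrow = TRUE)
  d_um <- sqrt(DY^2 + DX^2) * pixel_size
  theta <- atan2(DY, DX)
  list(rows = i0:i1, cols = j0:j1, patch = profile_fn(d_um, theta))
}

# Defocus: Gaussian blur radius grows linearly with height above the floor.
blur_sigma_um <- function(z_um, optics) optics$defocus_blur_coeff * z_um

# Irregular speck: a filled soft blob whose boundary radius is modulated by
# low-order angular harmonics.  Debris is amorphous, not circular: the
# counting algorithm relies on debris and clumps having a low degree of
# radial symmetry, and the renderer honours that.
debris_profile <- function(r_um, edge_w_um) {
  ph <- runif(3, 0, 2 * pi)
  function(d_um, theta) {
    rb <- r_um * (1 + 0.30 * sin(2 * theta + ph[1]) +
                    0.22 * sin(3 * theta + ph[2]) +
                    0.15 * sin(5 * theta + ph[3]))
    1 / (1 + exp((d_um - rb) / edge_w_um))
  }
}

# Multi-lobed clump silhouette: union of 2-4 offset soft blobs whose radii
# are modulated by low-order angular harmonics, giving the low radial
# symmetry that keeps clumps below the detector's sensitivity threshold.
clump_profile <- function(r_um, edge_w_um) {
  n_lobes <- sample(2:4, 1)
  ang <- runif(n_lobes, 0, 2 * pi)
  rho <- runif(n_lobes, 0.2, 0.45) * r_um
  lrad <- runif(n_lobes, 0.5, 0.75) * r_um
  ph1 <- runif(n_lobes, 0, 2 * pi)
  ph2 <- runif(n_lobes, 0, 2 * pi)
  function(d_um, theta) {
    # positions relative to object centre
    X <- d_um * cos(theta); Y <- d_um * sin(theta)
    acc <- 0
    for (k in seq_len(n_lobes)) {
      xk <- X - rho[k] * cos(ang[k]); yk <- Y - rho[k] * sin(ang[k])
      dk <- sqrt(xk^2 + yk^2)
      tk <- atan2(yk, xk)
      rk <- lrad[k] * (1 + 0.22 * sin(3 * tk + ph1[k]) +
                         0.15 * sin(5 * tk + ph2[k]))
      acc <- pmax(acc, 1 / (1 + exp((dk - rk) / edge_w_um)))
    }
    acc
  }
}

#' Render the bright-field channel
#'
#' Draws all objects as dark features on a bright textured background: cells
#' as membrane-contrast annuli with a weaker interior shading, debris as
#' small irregular specks, clumps as multi-lobed blobs; debris and clumps
#' both have the low radial symmetry seen in real chambers.  The background
#' carries a mottled low-frequency texture and a faint periodic grid shadow
#' (the printing-layer artifact of 3D-printed chambers).  Objects floating
#' above the focal plane (the chamber floor) are blurred with a Gaussian of
#' standard deviation `defocus_blur_coeff * z` and proportionally reduced
#' contrast.  Additive Gaussian noise is applied last and intensities are
#' clipped to the bit depth.
#'
#' @param sample A `ground_truth_sample`.
#' @param optics An [optics_spec()]; defaults to the sample's own.
#' @param noise_sd Additive noise standard deviation (intensity units).
#' @param seed Optional seed for the stochastic scene dressing (texture,
#'   clump shapes, noise); identical seed, sample, and parameters give a
#'   bit-identical image.
#' @param bg_level Mean background intensity.
#' @param texture_amp,texture_scale Amplitude (intensity) and correlation
#'   length (px) of the background mottle.
#' @param grid_amp,grid_period,grid_width Amplitude (intensity), period (um),
#'   and line width (um) of the grid shadow.
#' @param ring_depth Contrast of an in-focus cell's membrane ring.
#' @param ring_sigma Radial width of the in-focus ring (um).
#' @param bit_depth Output bit depth (8 or 16).
#' @return An `image_frame` with modality `"bright_field"`.
#' @export
render_brightfield <- function(sample, optics = sample$optics,
                               noise_sd = simulator_params()$noise_sd_bf,
                               seed = NULL, bg_level = 30000,
                               texture_amp = 350, texture_scale = 24,
                               grid_amp = 700, grid_period = 22,
                               grid_width = 1.2, ring_depth = 9000,
                               ring_sigma = 0.45, bit_depth = 16) {
  stopifnot(inherits(sample, "ground_truth_sample"))
  H <- optics$height_px; W <- optics$width_px
  ps <- optics$pixel_size
  with_seed_if(seed, {
    img <- matrix(bg_level, H, W)
    img <- img + texture_amp * smooth_field(H, W, texture_scale)
    img <- img - grid_amp * grid_pattern(H, W, grid_period / ps, grid_width / ps)

    obs <- sample$objects
    for (i in seq_len(nrow(obs))) {
      r <- obs$diameter_um[i] / 2
      sb <- blur_sigma_um(obs$z_um[i], optics)
      sigma_e <- sqrt(ring_sigma^2 + sb^2)
      depth <- ring_depth * ring_sigma / sigma_e   # contrast fades with blur
      cx <- um_to_col(obs$x_um[i], ps); cy <- um_to_row(obs$y_um[i], ps)
      if (obs$class[i] == "clump") {
        prof_fun <- clump_profile(r, max(0.8, sigma_e))
        fn <- function(d, th) depth * prof_fun(d, th)
        extent <- (1.5 * r + 3 * sigma_e) / ps + 2
      } else if (obs$class[i] == "debris") {
        prof_fun <- debris_profile(r, max(0.4, sigma_e * 0.7))
        fn <- function(d, th) 0.8 * depth * prof_fun(d, th)
        extent <- (1.5 * r + 3 * sigma_e) / ps + 2
      } else {
        # membrane ring centred one ring-width inside the boundary, so the
        # outer gradient edge sits at the declared apparent radius r
        r_ring <- max(r - sigma_e, 0.5 * r)
        core_sigma <- r / 1.6
        fn <- function(d, th) {
          depth * exp(-(d - r_ring)^2 / (2 * sigma_e^2)) +
            0.25 * depth * exp(-d^2 / (2 * core_sigma^2))
        }
        extent <- (r + 3.5 * sigma_e) / ps + 2
      }
      p <- object_patch(c(H, W), cx, cy, extent, ps, fn)
      if (!is.null(p)) img[p$rows, p$cols] <- img[p$rows, p$cols] - p$patch
    }

    if (noise_sd > 0) img <- img + rnorm(H * W, sd = noise_sd)
    img <- round(pmin(pmax(img, 0), 2^bit_depth - 1))
    image_frame(img, pixel_size = ps, modality = "bright_field",
                bit_depth = bit_depth)
  })
}

#' Render the fluorescence channel
#'
#' Only WBCs appear: the nuclear stain is DNA-selective, so anucleate RBCs,
#' debris, and clumps contribute nothing above background.  Each WBC is a
#' soft-edged bright disk of amplitude [staining_signal()]; the background is
#' `bg_floor + bg_slope * c_d`.  Defocus follows the same rule as the
#' bright-field channel.
#'
#' @inheritParams render_brightfield
#' @param staining A [staining_condition()].
#' @param model A [staining_model_params()].
#' @param edge_width In-focus softness of the spot edge (um).
#' @return An `image_frame` with modality `"fluorescence"`.
#' @export
render_fluorescence <- function(sample, optics = sample$optics,
                                staining = staining_condition(),
                                model = staining_model_params(),
                                noise_sd = simulator_params()$noise_sd_fl,
                                seed = NULL, edge_width = 0.6,
                                bit_depth = 16) {
  stopifnot(inherits(sample, "ground_truth_sample"),
            inherits(staining, "staining_condition"))
  H <- optics$height_px; W <- optics$width_px
  ps <- optics$pixel_size
  amp0 <- staining_signal(staining$c_d, staining$t_i, model)
  bg <- fluorescence_background(staining$c_d, model)
  with_seed_if(seed, {
    img <- matrix(bg, H, W)
    wbc <- sample$objects[sample$objects$class == "WBC", , drop = FALSE]
    for (i in seq_len(nrow(wbc))) {
      r <- wbc$diameter_um[i] / 2
      sb <- blur_sigma_um(wbc$z_um[i], optics)
      w <- sqrt(edge_width^2 + sb^2)
      amp <- amp0 * r^2 / (r^2 + 2 * sb^2)   # energy spreads with defocus
      cx <- um_to_col(wbc$x_um[i], ps); cy <- um_to_row(wbc$y_um[i], ps)
      fn <- function(d, th) amp / (1 + exp((d - r) / w))
      p <- object_patch(c(H, W), cx, cy, (r + 4 * w) / ps + 2, ps, fn)
      if (!is.null(p)) img[p$rows, p$cols] <- img[p$rows, p$cols] + p$patch
    }
    if (noise_sd > 0) img <- img + rnorm(H * W, sd = noise_sd)
    img <- round(pmin(pmax(img, 0), 2^bit_depth - 1))
    image_frame(img, pixel_size = ps, modality = "fluorescence",
                bit_depth = bit_depth)
  })
}

#' Truth-derived detections
#'
#' Converts a scene's ground truth into the detection-table shape, for
#' evaluation (matching detections to truth) and as a fallback where the
#' detector finds nothing (e.g. very dim staining conditions).
#'
#' @param sample A `ground_truth_sample`.
#' @param modality `"bright_field"` (all in-band cells) or `"fluorescence"`
#'   (WBCs only).
#' @return A detection tibble (`cx_um`, `cy_um`, `radius_um`, `score`,
#'   `modality`).
#' @export
detections_from_truth <- function(sample,
                                  modality = c("bright_field", "fluorescence")) {
  modality <- match.arg(modality)
  keep <- if (modality == "fluorescence") "WBC" else c("RBC", "WBC")
  obs <- sample$objects[sample$objects$class %in% keep, , drop = FALSE]
  tibble(cx_um = obs$x_um, cy_um = obs$y_um,
         radius_um = obs$diameter_um / 2, score = 1, modality = modality)
}

#' Simulate one paired-modality frame
#'
#' Convenience wrapper: samples a scene, settles it for `settle_time`
#' seconds at the configured settling velocity, and renders both channels.
#'
#' @param c_rbc,c_wbc True concentrations (cells/uL).
#' @param config A [default_config()]-style configuration.
#' @param seed Integer seed controlling the scene and both renderings.
#' @param settle_time Seconds of sedimentation before imaging; `Inf` (the
#'   default) images a fully settled chamber.
#' @return A list with elements `truth`, `bf`, `fl`.
#' @export
#' @examples
#' \donttest{
#' pair <- simulate_pair(100, 50, seed = 1)
#' pair$truth
#' }
simulate_pair <- function(c_rbc, c_wbc, config = default_config(), seed = NULL,
                          settle_time = Inf) {
  seeds <- if (is.null(seed)) list(NULL, NULL, NULL) else
    as.list(derive_seeds(seed, 3))
  truth <- sample_scene(c_rbc, c_wbc, config$optics, config$chamber,
                        config$simulator$debris_rate,
                        config$simulator$clump_rate,
                        sim = config$simulator, seed = seeds[[1]])
  if (is.infinite(settle_time)) {
    truth$objects$z_um <- 0 * truth$objects$z_um
  } else if (settle_time > 0) {
    v <- as.numeric(settling_velocity(config$sedimentation))
    truth <- settle(truth, settle_time, v)
  }
  bf <- render_brightfield(truth, config$optics,
                           noise_sd = config$simulator$noise_sd_bf,
                           seed = seeds[[2]])
  fl <- render_fluorescence(truth, config$optics, config$staining,
                            config$staining_model,
                            noise_sd = config$simulator$noise_sd_fl,
                            seed = seeds[[3]])
  list(truth = truth, bf = bf, fl = fl)
}

#' Write a simulated scene to disk
#'
#' Persists an image pair as 16-bit grayscale TIFFs (`<stem>_bf.tif`,
#' `<stem>_fl.tif`), the ground-truth object table as CSV, and a JSON
#' manifest recording seed and calibration.
#'
#' @param pair A list as returned by [simulate_pair()].
#' @param dir Output directory (created if needed).
#' @param stem Filename stem.
#' @return Named character vector of the paths written, invisibly.
#' @export
write_scene <- function(pair, dir, stem = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    bf = file.path(dir, paste0(stem, "_bf.tif")),
    fl = file.path(dir, paste0(stem, "_fl.tif")),
    truth = file.path(dir, paste0(stem, "_truth.csv")),
    manifest = file.path(dir, paste0(stem, "_manifest.json"))
  )
  write_image_frame(pair$bf, paths[["bf"]])
  write_image_frame(pair$fl, paths[["fl"]])
  utils::write.csv(pair$truth$objects, paths[["truth"]], row.names = FALSE)
  jsonlite::write_json(
    list(seed = pair$truth$seed,
         pixel_size_um = pair$truth$optics$pixel_size,
         fov_um = c(pair$truth$optics$fov_x, pair$truth$optics$fov_y),
         h_c_um = pair$truth$chamber$h_c,
         true_concentrations = as.list(pair$truth$true_concentrations)),
    paths[["manifest"]], auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}
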