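# End-to-end evaluation harness: synthetic dilution series, accuracy vs
# ground truth, and the file-based counting pipeline that the command-line
# interface wraps.

#' Synthetic dilution series
#'
#' Reproduces the platform-characterization experiment on simulated data:
#' for each expected concentration and replicate chamber, the configured
#' number of areas is simulated (fully settled scenes), both channels are
#' rendered and detected, counts are pooled into concentrations, and the
#' measured concentration is regressed on the expected one by ordinary
#' least squares (with intercept).  WBC and RBC series are run separately,
#' each with the other class absent, mirroring separately prepared cell
#' suspensions.
#'
#' The default series spans 5.2 to 1040 cells/uL in roughly 4-fold steps
#' with 3 replicate chambers per point.
#'
#' @param conc_list Expected concentrations (cells/uL), at least two
#'   distinct values.
#' @param n_replicates Replicate chambers per concentration.
#' @param config A [default_config()]-style configuration.
#' @param seed Integer seed; the whole series is deterministic given it.
#' @param cell_class Classes to run (`"WBC"`, `"RBC"`, or both).
#' @return An object of class `dilution_series`: replicate-level
#'   `measurements`, per-concentration `points` (mean, sd, cv), and a `fits`
#'   tibble (slope, intercept, r_squared per class).
#' @export
dilution_series <- function(conc_list = c(5.2, 16, 65, 260, 1040),
                            n_replicates = 3, config = default_config(),
                            seed = 1, cell_class = c("WBC", "RBC")) {
  if (length(unique(conc_list)) < 2) {
    abort_validation("need >= 2 distinct concentrations for a regression",
                     "conc_list")
  }
  if (any(conc_list < 0)) abort_validation("concentrations must be >= 0", "conc_list")
  check_number(n_replicates, "n_replicates", min = 1)
  cell_class <- match.arg(cell_class, several.ok = TRUE)

  n_runs <- length(cell_class) * length(conc_list) * n_replicates
  seeds <- derive_seeds(seed, n_runs)
  k <- 0L
  measurements <- list()
  for (cls in cell_class) {
    for (conc in conc_list) {
      for (rep_i in seq_len(n_replicates)) {
        k <- k + 1L
        res <- count_chamber(
          c_rbc = if (cls == "RBC") conc else 0,
          c_wbc = if (cls == "WBC") conc else 0,
          config = config, seed = seeds[k]
        )
        measurements[[k]] <- tibble(
          cell_class = cls, expected = conc, replicate = rep_i,
          measured = if (cls == "WBC") res$c_wbc else res$c_rbc
        )
      }
    }
  }
  measurements <- purrr::list_rbind(measurements)

  points <- measurements |>
    dplyr::summarise(
      measured_mean = mean(.data$measured),
      measured_sd = sd(.data$measured),
      cv = ifelse(mean(.data$measured) > 0,
                  sd(.data$measured) / mean(.data$measured), NA_real_),
      .by = c("cell_class", "expected")
    ) |>
    dplyr::arrange(.data$cell_class, .data$expected)

  fits <- measurements |>
    tidyr::nest(data = -"cell_class") |>
    dplyr::mutate(fit = purrr::map(.data$data, function(d) {
      m <- lm(measured ~ expected, data = d)
      tibble(slope = unname(coef(m)[2]), intercept = unname(coef(m)[1]),
             r_squared = summary(m)$r.squared)
    })) |>
    dplyr::select(-"data") |>
    tidyr::unnest("fit")

  structure(
    list(measurements = measurements, points = points, fits = fits,
         conc_list = sort(conc_list), n_replicates = n_replicates, seed = seed),
    class = "dilution_series"
  )
}

# Simulate and count one replicate chamber (n_areas frame pairs).
count_chamber <- function(c_rbc, c_wbc, config = default_config(), seed = 1,
                          settle_time = Inf, mode = "subtraction") {
  area_seeds <- derive_seeds(seed, config$chamber$n_areas)
  per_area <- purrr::map(area_seeds, function(s) {
    pair <- simulate_pair(c_rbc, c_wbc, config, seed = s,
                          settle_time = settle_time)
    count_area(find_circles(pair$bf, config$detection),
               find_circles(pair$fl, config$detection), mode = mode)
  }) |> purrr::list_rbind()
  concentrations(per_area, config$chamber)
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("<dilution_series> %d concentrations x %d replicates\n",
              length(x$conc_list), x$n_replicates))
  print(x$fits)
  invisible(x)
}

#' @export
#' @rdname dilution_series
#' @param x A `dilution_series`.
#' @param ... Unused.
tidy.dilution_series <- function(x, ...) x$points

#' @export
#' @rdname dilution_series
glance.dilution_series <- function(x, ...) x$fits

#' @export
autoplot.dilution_series <- function(object, ...) {
  ggplot2::ggplot(object$points,
                  ggplot2::aes(x = .data$expected, y = .data$measured_mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$measured_mean - .data$measured_sd,
      ymax = .data$measured_mean + .data$measured_sd)) +
    ggplot2::facet_wrap(~cell_class) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "expected concentration (cells/uL)",
                  y = "measured concentration (cells/uL)") +
    ggplot2::theme_minimal()
}

#' Counting accuracy against simulator truth
#'
#' Simulates `n_scenes` fully settled frame pairs at fixed concentrations,
#' counts them with the full pipeline, and scores each scene as
#' `1 - |pipeline - truth| / truth` on the total cell count (scenes with no
#' true cells are skipped).  Detection quality is summarized as the F1 of
#' bright-field detections matched to true cell positions within `tol` um,
#' pooled over scenes.
#'
#' @param n_scenes Number of independent scenes.
#' @param config A [default_config()]-style configuration.
#' @param seed Integer seed.
#' @param c_rbc,c_wbc Scene concentrations (cells/uL); the defaults emulate
#'   a model sample with moderate pleocytosis and mild blood contamination.
#' @param settle_time Seconds of sedimentation before imaging (default:
#'   fully settled).
#' @param tol Truth-matching tolerance (um).
#' @return An object of class `accuracy_result`: `per_scene` tibble,
#'   `mean_accuracy`, `f1`.
#' @export
accuracy_vs_truth <- function(n_scenes = 40, config = default_config(),
                              seed = 1, c_rbc = 100, c_wbc = 50,
                              settle_time = Inf, tol = 3) {
  check_number(n_scenes, "n_scenes", min = 1)
  seeds <- derive_seeds(seed, n_scenes)
  tp <- fp <- fn <- 0L
  per_scene <- purrr::map(seq_len(n_scenes), function(i) {
    pair <- simulate_pair(c_rbc, c_wbc, config, seed = seeds[i],
                          settle_time = settle_time)
    det <- find_circles(pair$bf, config$detection)
    truth_det <- detections_from_truth(pair$truth, "bright_field")
    m <- match_detections(det, truth_det, tol = tol)
    tp <<- tp + nrow(m$pairs)
    fp <<- fp + length(m$unmatched_a)
    fn <<- fn + length(m$unmatched_b)
    n_true <- nrow(truth_det)
    tibble(
      scene = i, n_true = n_true, n_detected = nrow(det),
      accuracy = if (n_true > 0) 1 - abs(nrow(det) - n_true) / n_true
                 else NA_real_
    )
  }) |> purrr::list_rbind()
  f1 <- if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  structure(
    list(per_scene = per_scene,
         mean_accuracy = mean(per_scene$accuracy, na.rm = TRUE),
         f1 = f1, tol = tol),
    class = "accuracy_result"
  )
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy_result> %d scene(s): mean accuracy %.4f, detection F1 %.4f\n",
              nrow(x$per_scene), x$mean_accuracy, x$f1))
  invisible(x)
}

#' @export
glance.accuracy_result <- function(x, ...) {
  tibble(n_scenes = nrow(x$per_scene), mean_accuracy = x$mean_accuracy,
         f1 = x$f1, tol_um = x$tol)
}

# Pair bright-field and fluorescence paths by filename stem (_bf/_fl suffix
# stripped); falls back to positional pairing with a warning when the
# suffixes are absent.
pair_frames <- function(bf_paths, fl_paths) {
  stem <- function(p, suffix) {
    s <- sub("\\.[^.]+$", "", basename(p))
    sub(paste0(suffix, "$"), "", s)
  }
  bf_stems <- stem(bf_paths, "_bf")
  fl_stems <- stem(fl_paths, "_fl")
  if (!length(bf_paths) || !length(fl_paths)) {
    abort_input("need at least one bright-field and one fluorescence frame")
  }
  if (anyDuplicated(bf_stems) || anyDuplicated(fl_stems) ||
      !setequal(bf_stems, fl_stems)) {
    orphans <- c(setdiff(bf_stems, fl_stems), setdiff(fl_stems, bf_stems))
    if (length(bf_paths) == length(fl_paths)) {
      warn(sprintf(
        "frame stems do not pair 1:1 (%s); falling back to positional pairing",
        paste(unique(orphans), collapse = ", ")))
      return(tibble(bf = bf_paths, fl = fl_paths))
    }
    abort_input(sprintf("cannot pair frames; unmatched stem(s): %s",
                        paste(unique(orphans), collapse = ", ")))
  }
  tibble(bf = bf_paths, fl = fl_paths[match(bf_stems, fl_stems)])
}

#' Run the counting pipeline on image files
#'
#' Reads paired bright-field/fluorescence frames, detects circular objects
#' in each, applies the counting rule per area, pools the areas into
#' concentrations, and assembles a JSON-ready report with parameters, input
#' checksums, warnings, and stage timings.
#'
#' @param bf_paths,fl_paths TIFF paths for the two channels, pairable by
#'   `_bf`/`_fl` filename stems or by position.
#' @param config A [default_config()]-style configuration.
#' @param mode Counting mode, see [count_area()].
#' @return A list of class `csf_report`.
#' @export
run_pipeline <- function(bf_paths, fl_paths, config = default_config(),
                         mode = "subtraction") {
  t0 <- Sys.time()
  pairs <- pair_frames(bf_paths, fl_paths)
  inform(sprintf("counting %d frame pair(s)", nrow(pairs)))
  detections <- list()
  per_area <- list()
  for (i in seq_len(nrow(pairs))) {
    ta <- Sys.time()
    bf <- read_image_frame(pairs$bf[i], config$optics$pixel_size, "bright_field")
    fl <- read_image_frame(pairs$fl[i], config$optics$pixel_size, "fluorescence")
    det_bf <- find_circles(bf, config$detection)
    det_fl <- find_circles(fl, config$detection)
    detections[[i]] <- list(area = i, bright_field = det_bf, fluorescence = det_fl)
    per_area[[i]] <- count_area(det_bf, det_fl, mode = mode)
    inform(sprintf("  area %d: %d bf / %d fl detections (%.2f s)", i,
                   nrow(det_bf), nrow(det_fl),
                   as.numeric(difftime(Sys.time(), ta, units = "secs"))))
  }
  per_area <- purrr::list_rbind(per_area)
  result <- concentrations(per_area, config$chamber)
  warnings <- character()
  if (any(per_area$clamped)) {
    warnings <- c(warnings, sprintf(
      "RBC count clamped at 0 in area(s) %s (fluorescence count exceeded bright-field count)",
      paste(which(per_area$clamped), collapse = ", ")))
  }
  cfg_flat <- local({
    km <- config_key_map()
    out <- list()
    for (comp in names(km)) for (key in km[[comp]]) {
      out[[key]] <- config[[comp]][[key]]
    }
    out
  })
  report <- structure(
    list(
      tool = "csfcount",
      version = as.character(utils::packageVersion("csfcount")),
      inputs = list(
        bright_field = unname(pairs$bf), fluorescence = unname(pairs$fl),
        md5 = as.list(tools::md5sum(c(pairs$bf, pairs$fl)))
      ),
      parameters = cfg_flat,
      mode = mode,
      per_area = per_area,
      detections = detections,
      concentrations = list(
        c_total = result$c_total, c_wbc = result$c_wbc, c_rbc = result$c_rbc,
        cv_total = result$cv_total, cv_wbc = result$cv_wbc,
        cv_rbc = result$cv_rbc,
        analysis_volume_nl = result$analysis_volume
      ),
      warnings = warnings,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    ),
    class = "csf_report"
  )
  inform(sprintf("done in %.2f s: c_wbc = %.2f, c_rbc = %.2f cells/uL",
                 report$elapsed_s, result$c_wbc, result$c_rbc))
  report
}

#' Write a pipeline report as JSON
#'
#' @param report A `csf_report` from [run_pipeline()].
#' @param path Output path.
#' @param timestamps Include the wall-clock timing field (`FALSE` gives
#'   byte-identical reports for identical inputs).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, timestamps = TRUE) {
  out <- unclass(report)
  out$detections <- purrr::map(report$detections, function(d) {
    list(area = d$area, bright_field = d$bright_field,
         fluorescence = d$fluorescence)
  })
  if (!timestamps) out$elapsed_s <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
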