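# Staining quality control: fluorescence signal-to-noise measurement and
# protocol optimization.  SNR is defined as the ratio of mean in-cell
# fluorescence to the robust background level, matching the ">= 5.4" scale
# on which staining protocols are judged.

#' Measure fluorescence signal-to-noise
#'
#' Signal is the mean intensity over pixels inside the detection circles;
#' background is the median intensity over pixels farther than
#' `radius + margin` from every detection centre.  A zero background is
#' floored at 1 intensity unit with a warning, so the ratio stays finite.
#'
#' @param fl A fluorescence [image_frame()].
#' @param detections Detection tibble (`cx_um`, `cy_um`, `radius_um`); truth
#'   positions via [detections_from_truth()] are an accepted fallback when
#'   the detector finds nothing.
#' @param margin Exclusion margin around each cell for the background
#'   region (um).
#' @return A one-row tibble of class `snr_result`: `signal`, `background`,
#'   `snr`, `n_cells`.
#' @export
measure_snr <- function(fl, detections, margin = 2) {
  stopifnot(inherits(fl, "image_frame"))
  check_number(margin, "margin", min = 0)
  if (is.null(detections) || nrow(detections) == 0) {
    abort("SNR needs at least one detection; pass truth positions as fallback",
          class = "csfcount_measurement_error")
  }
  px <- fl$pixels
  ps <- fl$pixel_size
  H <- nrow(px); W <- ncol(px)
  in_cell <- matrix(FALSE, H, W)
  excluded <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(detections))) {
    cx <- um_to_col(detections$cx_um[i], ps)
    cy <- um_to_row(detections$cy_um[i], ps)
    r_px <- detections$radius_um[i] / ps
    ex_px <- (detections$radius_um[i] + margin) / ps
    i0 <- max(1L, floor(cy - ex_px)); i1 <- min(H, ceiling(cy + ex_px))
    j0 <- max(1L, floor(cx - ex_px)); j1 <- min(W, ceiling(cx + ex_px))
    if (i0 > i1 || j0 > j1) next
    DY <- matrix((i0:i1) - cy, i1 - i0 + 1L, j1 - j0 + 1L)
    DX <- matrix((j0:j1) - cx, i1 - i0 + 1L, j1 - j0 + 1L, byrow = TRUE)
    d2 <- DY^2 + DX^2
    in_cell[i0:i1, j0:j1] <- in_cell[i0:i1, j0:j1] | (d2 <= r_px^2)
    excluded[i0:i1, j0:j1] <- excluded[i0:i1, j0:j1] | (d2 <= ex_px^2)
  }
  signal <- mean(px[in_cell])
  bg_px <- px[!excluded]
  background <- if (length(bg_px)) median(bg_px) else 0
  if (background <= 0) {
    warn("background is zero; flooring at 1 intensity unit",
         class = "csfcount_background_floor_warning")
    background <- 1
  }
  structure(
    tibble(signal = signal, background = background,
           snr = signal / background, n_cells = nrow(detections)),
    class = c("snr_result", class(tibble()))
  )
}

#' Sweep staining conditions on a fixed scene
#'
#' Renders the same ground-truth scene under each staining condition (same
#' rendering seed throughout, so only the staining varies), runs circle
#' detection on each fluorescence frame, and measures the SNR.  Where the
#' detector finds no cells (very dim conditions) the measurement falls back
#' to the ground-truth WBC positions, recorded in the `source` column.
#'
#' @param conditions A data frame with columns `c_d` (uM) and `t_i` (min),
#'   or a list of [staining_condition()] objects.
#' @param scene A `ground_truth_sample` containing at least one WBC
#'   (typically fully settled).
#' @param model A [staining_model_params()].
#' @param seed Integer seed for the rendering noise (shared across
#'   conditions).
#' @param params A [detection_params()].
#' @param noise_sd Fluorescence noise level (intensity units).
#' @param margin Background exclusion margin (um), see [measure_snr()].
#' @return A tibble of class `snr_sweep`, sorted by `(c_d, t_i)`:
#'   `c_d`, `t_i`, `signal`, `background`, `snr`, `n_cells`, `source`.
#' @export
sweep_conditions <- function(conditions, scene, model = staining_model_params(),
                             seed = 1, params = detection_params(),
                             noise_sd = simulator_params()$noise_sd_fl,
                             margin = 2) {
  stopifnot(inherits(scene, "ground_truth_sample"))
  if (inherits(conditions, "staining_condition")) conditions <- list(conditions)
  if (is.list(conditions) && !is.data.frame(conditions)) {
    conditions <- purrr::map(conditions, \(x) tibble(c_d = x$c_d, t_i = x$t_i)) |>
      purrr::list_rbind()
  }
  conditions <- as_tibble(conditions)
  if (!nrow(conditions)) abort_validation("`conditions` must be nonempty", "conditions")
  if (!all(c("c_d", "t_i") %in% names(conditions))) {
    abort_validation("`conditions` needs columns `c_d` and `t_i`", "conditions")
  }
  rows <- purrr::pmap(conditions, function(c_d, t_i, ...) {
    cond <- staining_condition(c_d = c_d, t_i = t_i)
    fl <- render_fluorescence(scene, scene$optics, cond, model,
                              noise_sd = noise_sd, seed = seed)
    det <- find_circles(fl, params)
    src <- "detected"
    if (nrow(det) == 0) {
      det <- detections_from_truth(scene, "fluorescence")
      src <- "truth"
    }
    if (nrow(det) == 0) {
      abort("scene contains no WBCs; SNR is undefined",
            class = "csfcount_measurement_error")
    }
    snr <- measure_snr(fl, det, margin = margin)
    dplyr::mutate(as_tibble(snr), c_d = c_d, t_i = t_i, source = src,
                  .before = 1)
  })
  out <- purrr::list_rbind(rows) |> dplyr::arrange(.data$c_d, .data$t_i)
  class(out) <- c("snr_sweep", class(out))
  out
}

#' Recommend the staining optimum
#'
#' From a sweep table: the optimal dye concentration is the one whose
#' (best observed) SNR is maximal, ties resolved toward the lower
#' concentration; the optimal incubation time is the earliest `t_i` whose
#' signal reaches 95% of the plateau (maximum observed) signal, judged
#' among rows at the chosen concentration when several concentrations were
#' swept.
#'
#' @param sweep An `snr_sweep` tibble from [sweep_conditions()].
#' @return A list with elements `c_d` (uM) and `t_i` (min).
#' @export
recommend_optimum <- function(sweep) {
  sweep <- as_tibble(sweep)
  if (!nrow(sweep)) abort_validation("`sweep` must be nonempty", "sweep")
  by_cd <- sweep |>
    dplyr::summarise(snr = max(.data$snr), .by = "c_d") |>
    dplyr::arrange(.data$c_d)
  c_d_opt <- by_cd$c_d[which.max(by_cd$snr)]   # which.max takes the first tie

  rows <- sweep[sweep$c_d == c_d_opt, , drop = FALSE]
  if (nrow(rows) < 2) rows <- sweep
  plateau <- max(rows$signal)
  ok <- rows$t_i[rows$signal >= 0.95 * plateau]
  list(c_d = c_d_opt, t_i = min(ok))
}

#' @export
autoplot.snr_sweep <- function(object, ...) {
  n_cd <- length(unique(object$c_d))
  if (n_cd > 1) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data$c_d, y = .data$snr)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "dye concentration (uM)", y = "SNR",
                    title = "Staining signal-to-noise vs dye concentration") +
      ggplot2::theme_minimal()
  } else {
    long <- tidyr::pivot_longer(object, c("signal", "snr"),
                                names_to = "quantity")
    ggplot2::ggplot(long, ggplot2::aes(x = .data$t_i, y = .data$value)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::facet_wrap(~quantity, scales = "free_y") +
      ggplot2::labs(x = "incubation time (min)", y = NULL,
                    title = "Staining kinetics") +
      ggplot2::theme_minimal()
  }
}
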