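# Circle Hough transform detection of cell-like objects.
#
# The counting program identifies cells by their radial symmetry and size:
# edge pixels vote for circle centres displaced +/- r along their gradient
# direction for every candidate radius r; votes are pooled and normalized so
# a clean full circle scores ~1; peaks above the sensitivity threshold,
# pruned by non-maximum suppression and confined to the apparent-diameter
# band, become detections.  Debris (too small), clumps (too large, low
# radial symmetry), and background texture all fall outside the gate.

#' Gradient edge map
#'
#' Computes the intensity gradient by central differences after 3x3 binomial
#' smoothing, and an edge mask of the pixels whose gradient magnitude
#' exceeds the given percentile of nonzero magnitudes.  A constant image
#' yields an empty mask (no error).
#'
#' The reference magnitude `mag_ref` is carried along: Hough votes are
#' weighted by `magnitude / mag_ref`, so accumulator scores express edge
#' contrast relative to a nominal in-focus object edge.  By default the
#' reference is supplied by the caller (the instrument's calibrated
#' per-channel constant, see [detection_params()]); when absent it is
#' estimated from the frame as the 99.9th percentile of magnitudes inside
#' the mask (the peak gradient of the frame's strongest edges).
#'
#' @param image An [image_frame()].
#' @param edge_percentile Percentile of nonzero gradient magnitudes below
#'   which pixels are excluded from the edge mask.
#' @param gradient_ref Calibrated reference gradient (intensity per px), or
#'   `NULL` to estimate it from the frame.
#' @return An object of class `edge_map`: gradient components `gx`, `gy`
#'   (intensity per px), magnitude `mag`, logical `mask`, `mag_ref`, and the
#'   pixel calibration.
#' @export
edge_map <- function(image, edge_percentile = 0.95, gradient_ref = NULL) {
  stopifnot(inherits(image, "image_frame"))
  check_number(edge_percentile, "edge_percentile", min = 0, max = 1)
  px <- image$pixels
  if (nrow(px) < 32 || ncol(px) < 32) {
    abort_validation("image must be at least 32 x 32 px", "image")
  }
  sm <- smooth3(px)
  H <- nrow(sm); W <- ncol(sm)
  gx <- matrix(0, H, W); gy <- matrix(0, H, W)
  gx[, 2:(W - 1)] <- (sm[, 3:W] - sm[, 1:(W - 2)]) / 2
  gy[2:(H - 1), ] <- (sm[3:H, ] - sm[1:(H - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  mag[c(1, H), ] <- 0; mag[, c(1, W)] <- 0   # central differences undefined
  nz <- mag[mag > 0]
  if (!length(nz)) {
    mask <- matrix(FALSE, H, W)
    mag_ref <- 1
  } else {
    thr <- quantile(nz, edge_percentile, names = FALSE)
    mask <- mag > thr
    inmask <- mag[mask]
    mag_ref <- if (!is.null(gradient_ref)) {
      gradient_ref
    } else if (length(inmask)) {
      # fallback: peak gradient of the frame's strongest edges
      max(quantile(inmask, 0.999, names = FALSE), .Machine$double.eps)
    } else 1
  }
  structure(
    list(gx = gx, gy = gy, mag = mag, mask = mask, mag_ref = mag_ref,
         pixel_size = image$pixel_size, dim = c(H, W)),
    class = "edge_map"
  )
}

#' Candidate radii for a diameter band
#'
#' Strictly increasing radii spanning `[d_min/2, d_max/2]` in steps of
#' `radius_step`, with the upper endpoint appended when the step does not
#' land on it.
#'
#' @param params A [detection_params()].
#' @return Numeric vector of radii (um).
#' @export
candidate_radii <- function(params) {
  r <- seq(params$d_min / 2, params$d_max / 2 + 1e-9, by = params$radius_step)
  if (max(r) < params$d_max / 2 - 1e-9) r <- c(r, params$d_max / 2)
  r
}

#' Circle Hough accumulator
#'
#' Every edge pixel casts votes at the two candidate centres displaced
#' `+r` and `-r` along its gradient direction (both polarities, so dark
#' rings on a bright background and bright spots on a dark one share one
#' code path), for every candidate radius.  Votes are weighted by
#' `magnitude / mag_ref`, pooled over a 3x3 neighbourhood to absorb
#' rounding of sub-pixel centres, and each radius slice is divided by the
#' ideal vote mass of a full circle of that radius, so a clean complete
#' circle peaks near 1 regardless of its size.
#'
#' @param edges An [edge_map()].
#' @param radii Candidate radii (um), strictly increasing.
#' @param pixel_size Pixel pitch (um per pixel); defaults to the edge map's.
#' @return A 3-D array (rows, columns, radius index) of normalized scores,
#'   with attribute `radii`.
#' @export
hough_accumulate <- function(edges, radii, pixel_size = edges$pixel_size) {
  stopifnot(inherits(edges, "edge_map"))
  if (!length(radii) || is.unsorted(radii, strictly = TRUE)) {
    abort_validation("`radii` must be nonempty and strictly increasing", "radii")
  }
  H <- edges$dim[1]; W <- edges$dim[2]
  acc <- array(0, dim = c(H, W, length(radii)))
  attr(acc, "radii") <- radii
  idx <- which(edges$mask)
  if (!length(idx)) return(acc)

  ey <- ((idx - 1L) %% H) + 1L
  ex <- ((idx - 1L) %/% H) + 1L
  m <- edges$mag[idx]
  ux <- edges$gx[idx] / m
  uy <- edges$gy[idx] / m
  # linear weights: the radial line integral of gradient magnitude across an
  # edge equals its intensity contrast, so vote mass measures edge strength
  w <- m / edges$mag_ref

  # Ideal concentrated vote mass of a complete circle is kappa * 2 pi r:
  # the smoothed central-difference edge of a boundary is ~2 px thick, but
  # only the votes from the radially coherent part of that band land within
  # the 3x3 pooling window (ring-profiled objects present two offset edges,
  # of which one concentrates per candidate radius), giving kappa < 2.
  kappa <- 1.4
  for (k in seq_along(radii)) {
    r_px <- radii[k] / pixel_size
    pooled <- cht_vote_pool(ey, ex, uy, ux, w, r_px, H, W) /
      (kappa * 2 * pi * r_px)
    # the maximum attainable vote shrinks near the image border, where part
    # of the circle lies outside the field: scale the border bands by the
    # visible arc fraction (row and column factors combined multiplicatively,
    # a close approximation except in the rare far corners; each factor is
    # floored at 0.5)
    visible <- function(t) {
      pmax(0.5, 1 - 2 * acos(pmin(t / r_px, 1)) / (2 * pi))
    }
    b <- min(ceiling(r_px), H %/% 2, W %/% 2)
    rows <- c(seq_len(b), H - b + seq_len(b))
    cols <- c(seq_len(b), W - b + seq_len(b))
    fy <- visible(c(0:(b - 1), (b - 1):0))
    pooled[rows, ] <- pooled[rows, ] / fy
    pooled[, cols] <- sweep(pooled[, cols, drop = FALSE], 2, fy, "/")
    acc[, , k] <- pooled
  }
  acc
}

#' Detect circular objects
#'
#' The full detection pipeline: [edge_map()], [hough_accumulate()] over the
#' diameter band's candidate radii, then peak extraction.  Peaks are local
#' maxima of the accumulator over their 3x3x3 neighbourhood with normalized
#' score at or above `sensitivity_threshold`; greedy non-maximum suppression
#' in descending score order removes any peak whose centre lies within
#' `min_center_distance` of an already accepted one.  Detections are
#' reported in um and ordered deterministically (descending score, ties by
#' row-major centre position).
#'
#' @param image An [image_frame()].
#' @param params A [detection_params()].
#' @return A tibble of detections: `cx_um`, `cy_um`, `radius_um`, `score`
#'   (clamped to \[0, 1\]), `modality`.
#' @export
#' @examples
#' truth <- ground_truth_sample(
#'   tibble::tibble(x_um = 300, y_um = 230, z_um = 0,
#'                  class = "RBC", diameter_um = 11),
#'   optics = optics_spec()
#' )
#' bf <- render_brightfield(truth, noise_sd = 0, seed = 1)
#' find_circles(bf, detection_params())
find_circles <- function(image, params = detection_params()) {
  stopifnot(inherits(image, "image_frame"), inherits(params, "detection_params"))
  ps <- image$pixel_size
  if (min(dim(image$pixels)) * ps < params$d_max) {
    abort_validation("image is smaller than `d_max`; nothing can be detected",
                     "image")
  }
  gref <- if (image$modality == "fluorescence") params$gradient_ref_fl
          else params$gradient_ref_bf
  edges <- edge_map(image, params$edge_percentile, gradient_ref = gref)
  radii <- candidate_radii(params)
  acc <- hough_accumulate(edges, radii, ps)
  H <- dim(acc)[1]; W <- dim(acc)[2]; R <- dim(acc)[3]

  # threshold first, then keep the 3x3x3 local maxima among the candidates
  cand <- which(acc >= params$sensitivity_threshold)
  if (!length(cand)) {
    return(tibble(cx_um = numeric(), cy_um = numeric(), radius_um = numeric(),
                  score = numeric(), modality = character()))
  }
  kk <- ((cand - 1L) %/% (H * W)) + 1L
  rem <- (cand - 1L) %% (H * W)
  cc <- (rem %/% H) + 1L
  rr <- (rem %% H) + 1L
  val <- acc[cand]
  is_max <- rep(TRUE, length(cand))
  for (dk in -1:1) for (dx in -1:1) for (dy in -1:1) {
    if (dk == 0 && dx == 0 && dy == 0) next
    ok <- rr + dy >= 1L & rr + dy <= H & cc + dx >= 1L & cc + dx <= W &
      kk + dk >= 1L & kk + dk <= R
    if (!any(ok)) next
    neigh <- cand[ok] + dy + dx * H + dk * (H * W)
    is_max[ok] <- is_max[ok] & val[ok] >= acc[neigh]
  }
  cand <- cand[is_max]
  rr <- rr[is_max]; cc <- cc[is_max]; kk <- kk[is_max]
  sc <- val[is_max]
  ord <- order(-sc, rr, cc, kk)
  rr <- rr[ord]; cc <- cc[ord]; kk <- kk[ord]; sc <- sc[ord]

  # greedy non-maximum suppression by centre distance (um)
  xs <- col_to_um(cc, ps); ys <- row_to_um(rr, ps)
  keep <- logical(length(sc))
  acc_x <- numeric(0); acc_y <- numeric(0)
  for (i in seq_along(sc)) {
    if (!length(acc_x) ||
        all((xs[i] - acc_x)^2 + (ys[i] - acc_y)^2 >=
              params$min_center_distance^2)) {
      keep[i] <- TRUE
      acc_x <- c(acc_x, xs[i]); acc_y <- c(acc_y, ys[i])
    }
  }
  tibble(
    cx_um = xs[keep], cy_um = ys[keep], radius_um = radii[kk[keep]],
    score = pmin(1, sc[keep]), modality = image$modality
  )
}

#' Match two detection sets
#'
#' Greedy nearest-neighbour one-to-one pairing by centre distance: the
#' globally closest pair is matched first, each detection is used at most
#' once, and pairs farther apart than `tol` are rejected.
#'
#' @param a,b Detection tibbles (columns `cx_um`, `cy_um`).
#' @param tol Maximum pairing distance (um).
#' @return A list with `pairs` (tibble `idx_a`, `idx_b`, `dist_um`),
#'   `unmatched_a`, and `unmatched_b` (integer row indices).
#' @export
match_detections <- function(a, b, tol) {
  check_number(tol, "tol", min = 0, strict_min = TRUE)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0 || nb == 0) {
    return(list(pairs = tibble(idx_a = integer(), idx_b = integer(),
                               dist_um = numeric()),
                unmatched_a = seq_len(na), unmatched_b = seq_len(nb)))
  }
  d <- outer(a$cx_um, b$cx_um, "-")^2 + outer(a$cy_um, b$cy_um, "-")^2
  d <- sqrt(d)
  pairs <- list()
  repeat {
    mn <- min(d)
    if (!is.finite(mn) || mn > tol) break
    hit <- which(d == mn, arr.ind = TRUE)[1, , drop = TRUE]
    pairs[[length(pairs) + 1L]] <-
      tibble(idx_a = unname(hit[1]), idx_b = unname(hit[2]), dist_um = mn)
    d[hit[1], ] <- Inf
    d[, hit[2]] <- Inf
  }
  pairs <- if (length(pairs)) purrr::list_rbind(pairs) else
    tibble(idx_a = integer(), idx_b = integer(), dist_um = numeric())
  list(pairs = pairs,
       unmatched_a = setdiff(seq_len(na), pairs$idx_a),
       unmatched_b = setdiff(seq_len(nb), pairs$idx_b))
}

#' Overlay detections on an image
#'
#' Quick diagnostic plot: the image as a raster with detection circles on
#' top.
#'
#' @param image An [image_frame()].
#' @param detections A detection tibble from [find_circles()].
#' @param downsample Keep every n-th pixel for plotting speed.
#' @return A ggplot object.
#' @export
plot_detections <- function(image, detections, downsample = 2) {
  px <- image$pixels
  rows <- seq(1, nrow(px), by = downsample)
  cols <- seq(1, ncol(px), by = downsample)
  df <- expand.grid(y = row_to_um(rows, image$pixel_size),
                    x = col_to_um(cols, image$pixel_size))
  df$value <- as.vector(px[rows, cols])
  circ <- tidyr::crossing(detections, ang = seq(0, 2 * pi, length.out = 33)) |>
    dplyr::mutate(px_ = .data$cx_um + .data$radius_um * cos(.data$ang),
                  py_ = .data$cy_um + .data$radius_um * sin(.data$ang))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(x = .data$px_, y = .data$py_,
                                    group = interaction(.data$cx_um, .data$cy_um)),
                       colour = "red", linewidth = 0.3) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}
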