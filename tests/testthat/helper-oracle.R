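# Brute-force circle finder used as an independent oracle for the Hough
# detector.  Scores every (cx, cy, r) triple by the mean gradient-aligned
# edge support sampled along the circle perimeter, using Sobel gradients
# (a different edge operator than the implementation's smoothed central
# differences), then extracts peaks greedily.  Exhaustive and slow by
# design; only for small frames.

shift_mat <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  ys <- seq_len(H) + dy; xs <- seq_len(W) + dx
  ok_y <- ys >= 1 & ys <= H; ok_x <- xs >= 1 & xs <= W
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

sobel_gradients <- function(px) {
  gx <- (shift_mat(px, -1, 1) + 2 * shift_mat(px, 0, 1) + shift_mat(px, 1, 1) -
           shift_mat(px, -1, -1) - 2 * shift_mat(px, 0, -1) -
           shift_mat(px, 1, -1)) / 8
  gy <- (shift_mat(px, 1, -1) + 2 * shift_mat(px, 1, 0) + shift_mat(px, 1, 1) -
           shift_mat(px, -1, -1) - 2 * shift_mat(px, -1, 0) -
           shift_mat(px, -1, 1)) / 8
  list(gx = gx, gy = gy)
}

brute_force_circles <- function(frame, radii_um, n_peaks, min_sep_um = 8.6) {
  px <- frame$pixels
  ps <- frame$pixel_size
  g <- sobel_gradients(px)
  H <- nrow(px); W <- ncol(px)
  scores <- array(0, dim = c(H, W, length(radii_um)))
  for (k in seq_along(radii_um)) {
    r_px <- radii_um[k] / ps
    n_ang <- max(24L, round(2 * pi * r_px))
    ang <- seq(0, 2 * pi, length.out = n_ang + 1L)[-1]
    s <- matrix(0, H, W)
    for (a in ang) {
      dy <- as.integer(round(r_px * sin(a)))
      dx <- as.integer(round(r_px * cos(a)))
      s <- s + abs(shift_mat(g$gx, dy, dx) * cos(a) +
                     shift_mat(g$gy, dy, dx) * sin(a))
    }
    scores[, , k] <- s / n_ang
  }
  out <- list()
  for (p in seq_len(n_peaks)) {
    i <- which.max(scores)
    kk <- ((i - 1L) %/% (H * W)) + 1L
    rem <- (i - 1L) %% (H * W)
    cc <- (rem %/% H) + 1L
    rr <- (rem %% H) + 1L
    out[[p]] <- tibble::tibble(cx_um = (cc - 1) * ps, cy_um = (rr - 1) * ps,
                               radius_um = radii_um[kk])
    dy2 <- (matrix(seq_len(H), H, W) - rr)^2
    dx2 <- (matrix(seq_len(W), H, W, byrow = TRUE) - cc)^2
    supp <- dy2 + dx2 <= (min_sep_um / ps)^2
    for (k in seq_along(radii_um)) {
      sl <- scores[, , k]
      sl[supp] <- -Inf
      scores[, , k] <- sl
    }
  }
  dplyr::bind_rows(out)
}
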