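# Shared fixtures, all generated in code at test time.

# Optics for a square field of `px` pixels at the default pitch.
small_optics <- function(px = 128) {
  optics_spec(fov_x = px * 0.476, fov_y = px * 0.476, pixel_size = 0.476)
}

# Sharp-edged dark disks on a flat bright background, drawn directly
# (independently of the package renderer).
disk_frame <- function(centers_px, radii_px, size = 128, bg = 30000,
                       depth = 12000, noise_sd = 0, seed = 1,
                       pixel_size = 0.476) {
  img <- matrix(bg, size, size)
  for (i in seq_len(nrow(centers_px))) {
    dy <- matrix(seq_len(size) - centers_px[i, 2], size, size)
    dx <- matrix(seq_len(size) - centers_px[i, 1], size, size, byrow = TRUE)
    img[dy^2 + dx^2 <= radii_px[i]^2] <- bg - depth
  }
  if (noise_sd > 0) {
    img <- img + withr::with_seed(seed, matrix(rnorm(size^2, sd = noise_sd),
                                               size, size))
  }
  image_frame(round(pmin(pmax(img, 0), 65535)), pixel_size = pixel_size,
              modality = "bright_field", bit_depth = 16)
}

# Random non-overlapping in-band circle layouts for oracle comparisons:
# returns centres (px, can be fractional) and radii (px) for `n` circles.
random_circle_layout <- function(n, size = 128, r_range_px = c(9.5, 14.5),
                                 margin = 18, min_sep = 34) {
  repeat {
    cx <- runif(n, margin, size - margin)
    cy <- runif(n, margin, size - margin)
    if (n == 1 || min(dist(cbind(cx, cy))) >= min_sep) break
  }
  list(centers = cbind(cx, cy), radii = runif(n, r_range_px[1], r_range_px[2]))
}
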