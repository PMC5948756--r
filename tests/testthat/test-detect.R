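params <- detection_params()

test_that("edge map handles flat, step, and disk images correctly", {
  flat <- image_frame(matrix(1000, 64, 64), 0.476, "bright_field")
  e <- edge_map(flat)
  expect_equal(sum(e$mask), 0L)

  # vertical step edge: gradient direction horizontal along the step
  step <- matrix(100, 64, 64)
  step[, 33:64] <- 200
  es <- edge_map(image_frame(step, 0.476, "bright_field"))
  idx <- which(es$mask)
  ang <- abs(atan2(es$gy[idx], es$gx[idx])) * 180 / pi
  expect_true(all(pmin(ang, 180 - ang) < 5))

  # dark disk: edge mask concentrates on the boundary ring
  fr <- disk_frame(cbind(64, 64), 12, size = 128)
  ed <- edge_map(fr)
  idx <- which(ed$mask)
  H <- ed$dim[1]
  d_px <- sqrt((((idx - 1) %% H) + 1 - 64)^2 + (((idx - 1) %/% H) + 1 - 64)^2)
  expect_gte(mean(abs(d_px - 12) <= 1.5), 0.8)

  expect_error(edge_map(image_frame(matrix(0, 8, 8), 0.476, "bright_field")),
               class = "csfcount_validation_error")
})

test_that("the accumulator peaks at true centres and radii", {
  # pixel pitch chosen so the 12-px circle radius sits exactly on the
  # 5.8 um candidate
  fr <- disk_frame(cbind(64, 64), 12, size = 128, noise_sd = 120, seed = 3,
                   pixel_size = 5.8 / 12)
  radii <- candidate_radii(params)
  acc <- hough_accumulate(edge_map(fr, params$edge_percentile,
                                   params$gradient_ref_bf), radii)
  i <- which.max(acc)
  H <- dim(acc)[1]
  kk <- ((i - 1) %/% (H * dim(acc)[2])) + 1
  rem <- (i - 1) %% (H * dim(acc)[2])
  cc <- (rem %/% H) + 1
  rr <- (rem %% H) + 1
  expect_lte(max(abs(c(rr, cc) - 64)), 1)
  expect_equal(radii[kk], 5.8)
  expect_gte(max(acc), 0.8)

  # two disjoint circles give two separated maxima
  fr2 <- disk_frame(cbind(c(40, 92), c(40, 90)), c(11, 13), size = 128,
                    noise_sd = 120, seed = 4)
  det2 <- find_circles(fr2, params)
  expect_equal(nrow(det2), 2L)
  ord <- order(det2$cx_um)
  expect_lt(abs(det2$cx_um[ord[1]] - 39 * 0.476), 2 * 0.476)
  expect_lt(abs(det2$cx_um[ord[2]] - 91 * 0.476), 2 * 0.476)

  # an empty edge mask yields an all-zero accumulator
  e0 <- edge_map(image_frame(matrix(500, 64, 64), 0.476, "bright_field"))
  expect_true(all(hough_accumulate(e0, radii) == 0))
})

test_that("blank noise-only frames yield no detections", {
  img <- withr::with_seed(1, matrix(30000 + rnorm(128^2, sd = 300), 128, 128))
  fr <- image_frame(round(pmin(pmax(img, 0), 65535)), 0.476, "bright_field")
  expect_equal(nrow(find_circles(fr, params)), 0L)
})

test_that("rendered scenes are gated to in-band cells only", {
  sc <- scripted_scene(n_rbc = 5, n_wbc = 0, n_debris = 10, n_clump = 2,
                       seed = 21)
  bf <- render_brightfield(sc, seed = 22)
  det <- find_circles(bf, params)
  cells <- detections_from_truth(sc, "bright_field")
  expect_equal(nrow(det), nrow(cells))
  m <- match_detections(det, cells, tol = 2 * 0.476)
  expect_equal(nrow(m$pairs), nrow(cells))
  expect_true(all(det$score >= 0.9))
  expect_true(all(det$radius_um * 2 >= 8.6 & det$radius_um * 2 <= 14.2))
})

test_that("detection count is non-increasing in the sensitivity threshold", {
  sc <- scripted_scene(n_rbc = 6, n_debris = 6, n_clump = 2, seed = 31)
  bf <- render_brightfield(sc, seed = 32)
  counts <- vapply(c(0.3, 0.5, 0.7, 0.9, 0.95), function(th) {
    p <- detection_params(sensitivity_threshold = th)
    nrow(find_circles(bf, p))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("whole-pixel shifts translate detections exactly", {
  layout <- withr::with_seed(5, random_circle_layout(2))
  fr <- disk_frame(layout$centers, layout$radii, noise_sd = 100, seed = 6)
  det1 <- find_circles(fr, params)
  k <- 4L
  shifted <- fr$pixels[c((128 - k + 1):128, 1:(128 - k)),
                       c((128 - k + 1):128, 1:(128 - k))]
  fr2 <- image_frame(shifted, fr$pixel_size, "bright_field")
  det2 <- find_circles(fr2, params)
  expect_equal(nrow(det2), nrow(det1))
  o1 <- order(det1$cx_um); o2 <- order(det2$cx_um)
  expect_equal(det2$cx_um[o2], det1$cx_um[o1] + k * 0.476, tolerance = 1e-8)
  expect_equal(det2$cy_um[o2], det1$cy_um[o1] + k * 0.476, tolerance = 1e-8)
})

test_that("images smaller than the upper cut-off are rejected", {
  fr <- image_frame(matrix(100, 40, 40), pixel_size = 0.3,
                    modality = "bright_field")
  expect_error(find_circles(fr, params), class = "csfcount_validation_error")
})

test_that("greedy matching pairs nearest neighbours one-to-one", {
  a <- tibble::tibble(cx_um = c(10, 0, 20), cy_um = c(10, 0, 0))
  m <- match_detections(a, a, tol = 1)
  expect_equal(nrow(m$pairs), 3L)
  expect_true(all(m$pairs$dist_um == 0))

  b <- tibble::tibble(cx_um = 10, cy_um = 18)
  m2 <- match_detections(a[1, ], b, tol = 5)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(m2$unmatched_a, 1L)
  expect_equal(m2$unmatched_b, 1L)

  # two candidate assignments: the closer one must win
  a3 <- tibble::tibble(cx_um = c(0, 20), cy_um = c(0, 0))
  b3 <- tibble::tibble(cx_um = 1, cy_um = 0)
  m3 <- match_detections(a3, b3, tol = 25)
  expect_equal(m3$pairs$idx_a, 1L)
  expect_equal(m3$pairs$dist_um, 1)
  expect_equal(m3$unmatched_a, 2L)
})
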