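cfg <- default_config()

test_that("zero rates give an empty scene and negative rates error", {
  s <- sample_scene(0, 0, debris_rate = 0, clump_rate = 0, seed = 1)
  expect_equal(nrow(s$objects), 0L)
  expect_error(sample_scene(-1, 0), class = "csfcount_validation_error")
})

test_that("object loading is Poisson with mean = concentration x frame volume", {
  vol <- 610 * 460 * 532 / 1e9                      # 0.14927 uL per frame
  n_seeds <- 200
  counts <- t(vapply(seq_len(n_seeds), function(s) {
    obj <- sample_scene(1000, 5.2, seed = s)$objects
    c(rbc = sum(obj$class == "RBC"), wbc = sum(obj$class == "WBC"))
  }, c(rbc = 0, wbc = 0)))
  mu_rbc <- 1000 * vol                              # ~149.3
  mu_wbc <- 5.2 * vol                               # ~0.776
  expect_lt(abs(mean(counts[, "rbc"]) - mu_rbc), 3 * sqrt(mu_rbc / n_seeds))
  expect_lt(abs(mean(counts[, "wbc"]) - mu_wbc), 3 * sqrt(mu_wbc / n_seeds))
  # dispersion consistent with Poisson loading
  expect_gt(var(counts[, "rbc"]) / mean(counts[, "rbc"]), 0.7)
  expect_lt(var(counts[, "rbc"]) / mean(counts[, "rbc"]), 1.3)
})

test_that("identical seeds reproduce scenes and images bit for bit", {
  s1 <- sample_scene(100, 50, seed = 42)
  s2 <- sample_scene(100, 50, seed = 42)
  expect_identical(s1$objects, s2$objects)
  p1 <- simulate_pair(50, 20, cfg, seed = 9)
  p2 <- simulate_pair(50, 20, cfg, seed = 9)
  expect_identical(p1$bf$pixels, p2$bf$pixels)
  expect_identical(p1$fl$pixels, p2$fl$pixels)
})

test_that("settle lowers heights linearly and clamps at the floor", {
  s <- sample_scene(200, 100, seed = 3)
  s0 <- settle(s, 0, 0.92)
  expect_identical(s0$objects, s$objects)
  s1 <- settle(s, 300, 0.92)
  expect_equal(s1$objects$z_um, pmax(0, s$objects$z_um - 276))
  # complete sedimentation
  s2 <- settle(s, ceiling(532 / 0.92), 0.92)
  expect_true(all(s2$objects$z_um == 0))
  # worked case: z0 = 400 um, v = 0.92 um/s, t = 300 s -> 124 um
  one <- ground_truth_sample(tibble::tibble(
    x_um = 100, y_um = 100, z_um = 400, class = "RBC", diameter_um = 11))
  expect_equal(settle(one, 300, 0.92)$objects$z_um, 124)
})

test_that("staining signal follows the Hill x saturation model", {
  m <- staining_model_params()
  expect_equal(staining_signal(1e9, 1e9, m), m$s_max, tolerance = 1e-6)
  expect_equal(staining_signal(m$k_half, 1e9, m), m$s_max / 2, tolerance = 1e-6)
  expect_equal(staining_signal(750, 10, m),
               m$s_max * 0.5 * (1 - exp(-10 / m$tau)))
  expect_equal(staining_signal(0, 10, m), 0)
  # monotone nondecreasing in both arguments
  cd <- seq(0, 2000, by = 50)
  expect_true(all(diff(staining_signal(cd, 10, m)) >= 0))
  ti <- seq(0, 30, by = 0.5)
  expect_true(all(diff(staining_signal(750, ti, m)) >= 0))
})

test_that("the model SNR curve peaks at the half-saturation concentration", {
  m <- staining_model_params()
  cd <- c(25, 250, 500, 750, 1000, 1250)
  snr <- staining_signal(cd, 10, m) / (m$bg_floor + m$bg_slope * cd)
  expect_equal(cd[which.max(snr)], 750)
})

test_that("a rendered cell is a dark annulus at the truth position", {
  tr <- ground_truth_sample(
    tibble::tibble(x_um = 30.5, y_um = 30.5, z_um = 0, class = "RBC",
                   diameter_um = 11),
    optics = small_optics(), chamber = chamber_spec())
  bf <- render_brightfield(tr, noise_sd = 0, seed = 1)
  ps <- bf$pixel_size
  H <- nrow(bf$pixels)
  d <- sqrt((matrix((seq_len(H) - 1) * ps, H, H, byrow = TRUE) - 30.5)^2 +
              (matrix((seq_len(H) - 1) * ps, H, H) - 30.5)^2)
  prof <- tapply(as.vector(bf$pixels), cut(as.vector(d), seq(0, 12, 0.2)),
                 mean)
  r_min <- (seq(0.1, 11.9, 0.2))[which.min(prof)]
  expect_lt(abs(r_min - 5.5), 0.476)    # profile minimum at r within 1 px
})

test_that("defocus blur weakens edges monotonically with height", {
  grads <- vapply(c(0, 60, 150, 300), function(z) {
    tr <- ground_truth_sample(
      tibble::tibble(x_um = 30.5, y_um = 30.5, z_um = z, class = "RBC",
                     diameter_um = 11),
      optics = small_optics(), chamber = chamber_spec())
    bf <- render_brightfield(tr, noise_sd = 0, seed = 1,
                             texture_amp = 0, grid_amp = 0)
    max(edge_map(bf)$mag)
  }, numeric(1))
  expect_true(all(diff(grads) < 0))
})

test_that("only WBCs appear in the fluorescence channel", {
  tr <- sample_scene(300, 0, debris_rate = 50, clump_rate = 20, seed = 5)
  tr$objects$z_um <- 0
  m <- staining_model_params()
  fl <- render_fluorescence(tr, staining = staining_condition(750, 10),
                            model = m, noise_sd = 8, seed = 2)
  bg <- m$bg_slope * 750
  # RBC/debris/clump-only scene is statistically pure background
  expect_lt(abs(mean(fl$pixels) - bg), 2 * 8)
  expect_lt(max(fl$pixels), bg + 6 * 8)
  # with WBCs, bright spots appear exactly there
  tr2 <- tr
  tr2$objects$class[1:5] <- "WBC"
  fl2 <- render_fluorescence(tr2, staining = staining_condition(750, 10),
                             model = m, noise_sd = 8, seed = 2)
  expect_gt(max(fl2$pixels), bg + 100)
})

test_that("unstained chambers show no fluorescence signal", {
  tr <- ground_truth_sample(
    tibble::tibble(x_um = 30.5, y_um = 30.5, z_um = 0, class = "WBC",
                   diameter_um = 11),
    optics = small_optics(), chamber = chamber_spec())
  m <- staining_model_params()
  fl <- render_fluorescence(tr, staining = staining_condition(c_d = 0, t_i = 10),
                            model = m, noise_sd = 0, seed = 1)
  expect_equal(max(fl$pixels), m$bg_floor)
})

test_that("scripted scenes honour composition, clearance and the floor", {
  s <- scripted_scene(n_rbc = 5, n_wbc = 3, n_debris = 10, n_clump = 2,
                      seed = 7)
  expect_equal(as.vector(table(s$objects$class)[c("RBC", "WBC", "debris", "clump")]),
               c(5L, 3L, 10L, 2L))
  expect_true(all(s$objects$z_um == 0))
  d <- as.matrix(dist(s$objects[, c("x_um", "y_um")]))
  diag(d) <- Inf
  rr <- outer(s$objects$diameter_um, s$objects$diameter_um, "+") / 2
  expect_true(all(d >= rr + 5 - 1e-9))
})

test_that("image frames survive a TIFF round trip", {
  tr <- ground_truth_sample(
    tibble::tibble(x_um = 30.5, y_um = 30.5, z_um = 0, class = "RBC",
                   diameter_um = 11),
    optics = small_optics(), chamber = chamber_spec())
  bf <- render_brightfield(tr, noise_sd = 150, seed = 4)
  f <- withr::local_tempfile(fileext = ".tif")
  write_image_frame(bf, f)
  back <- read_image_frame(f, pixel_size = bf$pixel_size, "bright_field")
  expect_equal(back$pixels, bf$pixels)
})
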