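test_that("SNR of a uniform image is exactly 1", {
  fr <- image_frame(matrix(100, 128, 128), 0.476, "fluorescence")
  det <- tibble::tibble(cx_um = 30, cy_um = 30, radius_um = 5, score = 1,
                        modality = "fluorescence")
  res <- measure_snr(fr, det)
  expect_equal(res$snr, 1.0)
  expect_equal(res$n_cells, 1L)
})

test_that("SNR is signal mean over background median", {
  # flat spots of 200 on background 40 -> SNR 5
  img <- matrix(40, 128, 128)
  for (cpt in list(c(40, 40), c(90, 80))) {
    dy <- matrix(seq_len(128) - cpt[2], 128, 128)
    dx <- matrix(seq_len(128) - cpt[1], 128, 128, byrow = TRUE)
    img[dy^2 + dx^2 <= 14^2] <- 200
  }
  fr <- image_frame(img, 0.476, "fluorescence")
  det <- tibble::tibble(cx_um = (c(40, 90) - 1) * 0.476,
                        cy_um = (c(40, 80) - 1) * 0.476,
                        radius_um = 12 * 0.476, score = 1,
                        modality = "fluorescence")
  res <- measure_snr(fr, det, margin = 2)
  expect_equal(res$signal, 200)
  expect_equal(res$background, 40)
  expect_equal(res$snr, 5.0)
  expect_error(measure_snr(fr, det[0, ]),
               class = "csfcount_measurement_error")
})

test_that("SNR is invariant under global intensity scaling", {
  sc <- scripted_scene(n_rbc = 0, n_wbc = 8, n_debris = 0, n_clump = 0,
                       seed = 3)
  fl <- render_fluorescence(sc, staining = staining_condition(750, 10),
                            noise_sd = 8, seed = 4)
  det <- detections_from_truth(sc, "fluorescence")
  r1 <- measure_snr(fl, det)
  fl3 <- image_frame(3 * fl$pixels, fl$pixel_size, "fluorescence")
  r3 <- measure_snr(fl3, det)
  expect_equal(r3$snr, r1$snr, tolerance = 1e-12)
})

test_that("the background estimate is unbiased on pure background", {
  m <- staining_model_params()
  sc <- ground_truth_sample(
    tibble::tibble(x_um = 30, y_um = 30, z_um = 0, class = "WBC",
                   diameter_um = 11),
    optics = small_optics(), chamber = chamber_spec())
  fl <- render_fluorescence(sc, staining = staining_condition(750, 10),
                            model = m, noise_sd = 8, seed = 5)
  det <- detections_from_truth(sc, "fluorescence")
  res <- measure_snr(fl, det, margin = 3)
  # intensities are integers, so the median resolves the true level to 1 unit
  expect_lte(abs(res$background - m$bg_slope * 750), 1)
})

test_that("a single-condition sweep equals a direct measurement", {
  sc <- scripted_scene(n_rbc = 0, n_wbc = 6, n_debris = 0, n_clump = 0,
                       seed = 11)
  sw <- sweep_conditions(tibble::tibble(c_d = 750, t_i = 10), sc, seed = 12)
  expect_equal(nrow(sw), 1L)
  fl <- render_fluorescence(sc, staining = staining_condition(750, 10),
                            noise_sd = simulator_params()$noise_sd_fl,
                            seed = 12)
  direct <- measure_snr(fl, find_circles(fl, detection_params()))
  expect_equal(sw$snr, direct$snr)
  expect_equal(sw$source, "detected")
  expect_error(sweep_conditions(tibble::tibble(c_d = numeric(),
                                               t_i = numeric()), sc),
               class = "csfcount_validation_error")
})

test_that("the optimum rule takes the SNR argmax and the plateau knee", {
  sw <- tibble::tibble(c_d = c(250, 500, 750, 1000), t_i = 10,
                       signal = c(100, 300, 500, 600),
                       background = c(30, 60, 90, 120),
                       snr = c(3.3, 5, 5.6, 5))
  expect_equal(recommend_optimum(sw)$c_d, 750)

  # strictly decreasing SNR: the lowest tested concentration wins
  sw2 <- dplyr::mutate(sw, snr = c(6, 5, 4, 3))
  expect_equal(recommend_optimum(sw2)$c_d, 250)

  # flat SNR ties resolve to the lower concentration
  sw3 <- dplyr::mutate(sw, snr = 5)
  expect_equal(recommend_optimum(sw3)$c_d, 250)

  # plateau rule: earliest time whose signal reaches 95% of the maximum
  sw4 <- tibble::tibble(c_d = 750, t_i = c(2, 4, 6, 8, 10, 15),
                        signal = c(452, 700, 836, 910, 950, 989),
                        background = 113,
                        snr = signal / background)
  expect_equal(recommend_optimum(sw4)$t_i, 10)
})
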