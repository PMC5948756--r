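# A reduced configuration (2 imaged areas) keeps the end-to-end tests quick;
# the acceptance suite exercises the full default study conditions.
quick_config <- function() {
  default_config(chamber = chamber_spec(h_c = 532, n_areas = 2,
                                        analysis_volume = 298.5))
}

test_that("a dilution series needs at least two distinct concentrations", {
  expect_error(dilution_series(conc_list = c(50, 50), n_replicates = 1),
               class = "csfcount_validation_error")
  expect_error(dilution_series(conc_list = c(-5, 50)),
               class = "csfcount_validation_error")
})

test_that("a small dilution series is deterministic and near-linear", {
  cfg <- quick_config()
  ds1 <- dilution_series(conc_list = c(30, 120), n_replicates = 2,
                         config = cfg, seed = 5, cell_class = "WBC")
  ds2 <- dilution_series(conc_list = c(30, 120), n_replicates = 2,
                         config = cfg, seed = 5, cell_class = "WBC")
  expect_identical(ds1$measurements, ds2$measurements)
  expect_equal(ds1$fits$cell_class, "WBC")
  expect_gt(ds1$fits$slope, 0.7)
  expect_lt(ds1$fits$slope, 1.3)
  expect_equal(nrow(tidy(ds1)), 2L)
  expect_named(glance(ds1), c("cell_class", "slope", "intercept", "r_squared"))
})

test_that("replicate scatter respects the Poisson counting floor", {
  cfg <- default_config(chamber = chamber_spec(h_c = 532, n_areas = 1,
                                               analysis_volume = 149.3))
  conc <- 65
  seeds <- withr::with_seed(77, sample.int(1e6, 12))
  meas <- vapply(seeds, function(s) {
    res <- csfcount:::count_chamber(c_rbc = 0, c_wbc = conc, config = cfg,
                                    seed = s)
    res$c_wbc
  }, numeric(1))
  cv <- sd(meas) / mean(meas)
  floor_cv <- poisson_cv(conc * 0.1493)
  expect_gte(cv, 0.5 * floor_cv)
})

test_that("WBC estimates ignore added RBC load", {
  cfg <- quick_config()
  r1 <- csfcount:::count_chamber(c_rbc = 0, c_wbc = 80, config = cfg, seed = 31)
  r2 <- csfcount:::count_chamber(c_rbc = 300, c_wbc = 80, config = cfg, seed = 31)
  n_expect <- 80 * 0.2985
  expect_lt(abs(r2$c_wbc - r1$c_wbc) * 0.2985, 3 * sqrt(2 * n_expect))
})

test_that("settled scenes are detected better than freshly loaded ones", {
  cfg <- quick_config()
  settled <- accuracy_vs_truth(4, cfg, seed = 7)
  fresh <- accuracy_vs_truth(4, cfg, seed = 7, settle_time = 0)
  expect_lt(fresh$f1, settled$f1)
})

test_that("frame pairing honours stems and falls back positionally", {
  p <- csfcount:::pair_frames(c("x/a1_bf.tif", "x/a2_bf.tif"),
                              c("y/a2_fl.tif", "y/a1_fl.tif"))
  expect_equal(basename(p$fl), c("a1_fl.tif", "a2_fl.tif"))
  expect_warning(
    p2 <- csfcount:::pair_frames(c("one.tif", "two.tif"),
                                 c("uno.tif", "dos.tif")),
    "positional")
  expect_equal(nrow(p2), 2L)
  expect_error(csfcount:::pair_frames(character(), character()),
               class = "csfcount_input_error")
  expect_error(csfcount:::pair_frames(c("a_bf.tif", "b_bf.tif"),
                                      "a_fl.tif"),
               class = "csfcount_input_error")
})

test_that("the file pipeline reproduces simulated concentrations", {
  cfg <- quick_config()
  dir <- withr::local_tempdir()
  for (i in 1:2) {
    pair <- simulate_pair(100, 50, cfg, seed = 40 + i)
    write_scene(pair, dir, stem = sprintf("area%d", i))
  }
  bf <- file.path(dir, sprintf("area%d_bf.tif", 1:2))
  fl <- file.path(dir, sprintf("area%d_fl.tif", 1:2))
  rep <- suppressMessages(run_pipeline(bf, fl, cfg))
  expect_s3_class(rep, "csf_report")
  expect_equal(nrow(rep$per_area), 2L)
  # within 3 Poisson standard deviations of the loaded concentrations
  n_total_exp <- 150 * 0.2985
  expect_lt(abs(rep$concentrations$c_total - 150) * 0.2985,
            3 * sqrt(n_total_exp))
  # reports are byte-identical apart from timing
  f1 <- file.path(dir, "r1.json"); f2 <- file.path(dir, "r2.json")
  write_report(rep, f1, timestamps = FALSE)
  rep2 <- suppressMessages(run_pipeline(bf, fl, cfg))
  write_report(rep2, f2, timestamps = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})
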