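test_that("rendering is deterministic given the seed", {
  spec <- synthetic_field_spec(
    size = c(120, 120),
    cells = list(synthetic_cell_spec(c(60, 60), c(14, 10),
                                     polarity_direction = 1,
                                     channels = list(cd44 = membrane_channel(kappa = 4)))),
    seed = 9)
  r1 <- render_field(spec)
  r2 <- render_field(spec)
  expect_identical(r1$field$channels, r2$field$channels)
  expect_identical(r1$mask, r2$mask)
})

test_that("a noise-free kappa = 0 membrane ring is angularly uniform", {
  spec <- synthetic_field_spec(
    size = c(100, 100),
    cells = list(synthetic_cell_spec(c(50, 50), c(20, 20),
      channels = list(ch = membrane_channel(kappa = 0, cytoplasm_level = 0,
                                            speckle_shape = Inf)))),
    background_level = 0, read_noise_sd = 0, shot_noise = FALSE, seed = 1)
  r <- render_field(spec)
  img <- r$field$channels$ch
  px <- which(img > 0, arr.ind = TRUE)
  th <- atan2(px[, 1] - 50, px[, 2] - 50)
  bins <- cut(th, breaks = seq(-pi, pi, length.out = 13))
  bin_mean <- tapply(img[px], bins, mean)   # per-pixel: bin areas differ
  expect_lt(max(bin_mean) / min(bin_mean), 1.1)
})

test_that("a kappa = 8 cap concentrates most membrane signal near mu", {
  mu <- pi / 3
  spec <- synthetic_field_spec(
    size = c(100, 100),
    cells = list(synthetic_cell_spec(c(50, 50), c(20, 20),
      polarity_direction = mu,
      channels = list(ch = membrane_channel(kappa = 8, cytoplasm_level = 0,
                                            speckle_shape = Inf)))),
    background_level = 0, read_noise_sd = 0, shot_noise = FALSE, seed = 1)
  r <- render_field(spec)
  img <- r$field$channels$ch
  px <- which(img > 0, arr.ind = TRUE)
  th <- atan2(px[, 1] - 50, px[, 2] - 50)
  dth <- atan2(sin(th - mu), cos(th - mu))
  frac <- sum(img[px][abs(dth) <= pi / 3]) / sum(img[px])
  # numerical von Mises integral: P(|theta - mu| <= 60 deg) at kappa = 8
  vm <- integrate(function(t) exp(8 * cos(t)) / (2 * pi * besselI(8, 0)),
                  -pi / 3, pi / 3)$value
  expect_gt(vm, 0.5)
  expect_gt(frac, 0.5)
  expect_equal(frac, vm, tolerance = 0.05)
})

test_that("overlapping cell placements are refused", {
  cells <- list(
    synthetic_cell_spec(c(30, 30), c(12, 10),
                        channels = list(ch = membrane_channel())),
    synthetic_cell_spec(c(34, 34), c(12, 10),
                        channels = list(ch = membrane_channel())))
  spec <- synthetic_field_spec(size = c(80, 80), cells = cells, seed = 1)
  expect_error(render_field(spec), "overlap")
  expect_error(simulate_field(60, size = c(150, 150), seed = 1),
               "crowded")
})

test_that("segmentation on noise-free renders recovers every cell almost exactly", {
  set.seed(2)
  sim_clean <- local({
    # noise-free variant: no shot noise, no read noise, smooth membrane
    simulate_field(6, size = c(250, 250), seed = 2,
                   channels = list(cd44 = membrane_channel(kappa = 0,
                                                           speckle_shape = Inf)),
                   read_noise_sd = 0, shot_noise = FALSE)
  })
  mask <- segment_field(sim_clean$field,
                        detection_params(detection_channel = "cd44"))
  expect_equal(max(mask), 6L)
  expect_true(all(match_iou(sim_clean$mask, mask) >= 0.95))
})

test_that("the truth table carries per-cell, per-channel kappa and mu", {
  sim <- simulate_field(4, size = c(220, 220), seed = 6,
                        channels = two_channel_specs(kappa_ref = 8,
                                                     kappa_marker = 2,
                                                     marker_offset = pi))
  expect_equal(nrow(sim$truth), 8)
  expect_setequal(unique(sim$truth$kappa), c(8, 2))
  off <- with(sim$truth,
              mu[channel == "marker"] - mu[channel == "cd44"])
  expect_true(all(abs(off - pi) < 1e-12))
})

test_that("benchmark datasets are reproducible on disk and pipeline-ready", {
  out1 <- file.path(tempdir(), "bench1"); out2 <- file.path(tempdir(), "bench2")
  unlink(c(out1, out2), recursive = TRUE)
  specs <- list(
    wt_like = list(channels = list(cd44 = membrane_channel(kappa = 4)),
                   n_fields = 2, cells_per_field = 4, size = c(200, 200),
                   tracks = list(n = 5, speed = 5, persistence = 0.7,
                                 n_frames = 10, dt = 10)),
    mutant_like = list(channels = list(cd44 = membrane_channel(kappa = 1)),
                       n_fields = 2, cells_per_field = 4,
                       size = c(200, 200)))
  make_benchmark(specs, out1, seed = 3)
  make_benchmark(specs, out2, seed = 3)
  expect_true(file.exists(file.path(out1, "config.yaml")))
  truth <- read.csv(file.path(out1, "wt_like", "truth.csv"))
  expect_equal(nrow(truth), 2 * 4)           # fields x cells (1 channel)
  expect_true(all(truth$kappa == 4))
  for (f in c("wt_like/field_01.tif", "wt_like/truth.csv",
              "wt_like/tracks.csv", "mutant_like/field_02.tif")) {
    expect_identical(unname(tools::md5sum(file.path(out1, f))),
                     unname(tools::md5sum(file.path(out2, f))))
  }
  # the written mask round-trips against the rendered truth
  m <- read_mask(file.path(out1, "wt_like", "mask_01.tif"))
  expect_equal(max(m), 4L)
})
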