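# Spot quantification: background correction, detection, IOD integration.

test_that("background correction removes flat backgrounds exactly", {
  flat <- gelprot:::gel_image(matrix(37.5, 120, 120))
  out <- correct_background(flat, radius = 20)
  expect_equal(max(abs(unclass(out))), 0)
  zero <- gelprot:::gel_image(matrix(0, 120, 120))
  expect_equal(max(abs(unclass(correct_background(zero, radius = 20)))), 0)
  expect_error(correct_background(flat, radius = 100), "larger than")
})

test_that("a Gaussian spot on constant background is recovered within 2%", {
  cfg <- simulation_config(
    n_spots = 1, image_dim = c(300, 300), noise_sd = 0,
    background_level = 55, edge_margin_px = 60,
    gel_scale_factors = c(case = 1, control = 1)
  )
  truth <- simulate_proteome(cfg, seed = 8)
  img <- render_gel(truth, "case", cfg, seed = 8)
  corrected <- correct_background(img)
  expect_lt(abs(sum(corrected) - truth$volume_case) / truth$volume_case,
            0.02)
})

test_that("detection finds well-separated spots and merges close peaks", {
  # volume floor set so every spot has peak SNR >= 10 at the default noise
  cfg <- simulation_config(
    n_spots = 50, image_dim = c(600, 600), min_separation_px = 30,
    edge_margin_px = 20, gel_scale_factors = c(case = 1, control = 1),
    volume_meanlog = log(6000), volume_min = 2000
  )
  scene <- simulate_gel_scene(cfg, seed = 13)
  q <- quantify_gel(scene$images$case, gel_id = "case", threshold_nmad = 6)
  det <- attr(q, "detections")
  expect_equal(nrow(det), 50)
  d <- sqrt(outer(scene$truth$row_px, det$row_px, "-")^2 +
              outer(scene$truth$col_px, det$col_px, "-")^2)
  expect_lt(max(apply(d, 1, min)), 2)

  # empty image: no detections
  empty <- correct_background(gelprot:::gel_image(matrix(0, 200, 200)),
                              radius = 20)
  expect_equal(nrow(detect_spots(empty)), 0)

  # two spots closer than min_separation merge into one seed
  two <- matrix(0, 200, 200)
  for (c0 in c(100, 104)) {
    rr <- 81:119; cc <- (c0 - 19):(c0 + 19)
    two[rr, cc] <- two[rr, cc] +
      2000 / (2 * pi * 6.25) * exp(-(outer((rr - 100)^2, (cc - c0)^2, "+")) /
                                     (2 * 2.5^2))
  }
  merged <- detect_spots(gelprot:::gel_image(two), min_separation = 8)
  expect_equal(nrow(merged), 1)
})

test_that("IOD integration is a masked sum with calibrated coordinates", {
  img <- gelprot:::gel_image(matrix(3, 20, 20),
                             calibration = list(ph_range = c(3, 10),
                                                mw_range = c(10, 100)))
  labels <- matrix(0L, 20, 20)
  labels[5, 1:10] <- 1L
  spots <- tibble::tibble(spot_id = c("D001", "D002"),
                          row_px = c(5, 15), col_px = c(5, 15),
                          pi = c(4, 8), mw_kda = c(80, 20),
                          peak = c(3, 0), n_px = c(10L, 0L))
  attr(spots, "labels") <- labels
  out <- integrate_iod(img, spots, gel_id = "g1")
  expect_equal(out$iod, c(30, 0))  # constant 3 over 10 px; empty mask
  expect_equal(out$gel_id, rep("g1", 2))
})

test_that("recovered IOD is conserved and linear in true volume", {
  # noiseless conservation over a full scene
  scene <- noiseless_scene()
  q <- quantify_gel(scene$images$case, gel_id = "case")
  expect_equal(nrow(q), nrow(scene$truth))
  expect_lt(abs(sum(q$iod) - sum(scene$truth$volume_case)) /
              sum(scene$truth$volume_case), 0.02)

  # volume ladder: regression slope within [0.95, 1.05]
  cfg <- simulation_config(
    n_spots = 24, image_dim = c(600, 600), min_separation_px = 40,
    edge_margin_px = 25, gel_scale_factors = c(case = 1, control = 1)
  )
  truth <- simulate_proteome(cfg, seed = 17)
  ladder <- 10^seq(log10(400), log10(40000), length.out = 24)
  truth$volume_case <- ladder
  img <- render_gel(truth, "case", cfg, seed = 17)
  q <- quantify_gel(img, gel_id = "ladder")
  det <- attr(q, "detections")
  d <- sqrt(outer(truth$row_px, det$row_px, "-")^2 +
              outer(truth$col_px, det$col_px, "-")^2)
  hit <- apply(d, 1, which.min)
  expect_true(all(d[cbind(seq_len(24), hit)] < 3))
  fit <- stats::lm(q$iod[hit] ~ ladder)
  expect_gt(coef(fit)[[2]], 0.95)
  expect_lt(coef(fit)[[2]], 1.05)
})

test_that("the default benchmark scene meets the detection targets", {
  m <- glance(benchmark_run())
  expect_gte(m$detection_recall_case, 0.95)
  expect_gte(m$detection_recall_control, 0.95)
  expect_gte(m$detection_precision_case, 0.95)
  expect_gte(m$detection_precision_control, 0.95)
})
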