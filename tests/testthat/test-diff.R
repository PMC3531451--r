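# ppm normalization, spot matching, fold classification, overlap,
# class proportions.

test_that("ppm normalization is proportional and scale-invariant", {
  x <- tibble::tibble(spot_id = as.character(1:3), gel_id = "g",
                      iod = c(100, 300, 600))
  out <- normalize_ppm(x)
  expect_equal(out$ppm, c(1e5, 3e5, 6e5))
  expect_equal(sum(out$ppm), 1e6)
  validate_spot_table(out, complete = TRUE)

  single <- normalize_ppm(tibble::tibble(spot_id = "1", gel_id = "g",
                                         iod = 7.3))
  expect_equal(single$ppm, 1e6)

  # invariance under global gel scaling, to 1e-9 relative
  set.seed(61)
  big <- tibble::tibble(spot_id = as.character(1:200), gel_id = "g",
                        iod = rlnorm(200, 5, 1.5))
  for (c0 in c(1e-6, 0.37, 12, 1e7)) {
    scaled <- dplyr::mutate(big, iod = iod * c0)
    expect_equal(normalize_ppm(scaled)$ppm, normalize_ppm(big)$ppm,
                 tolerance = 1e-9)
  }

  expect_error(normalize_ppm(tibble::tibble(spot_id = "1", gel_id = "g",
                                            iod = 0)), "zero total")
})

test_that("id-keyed matching pairs the fixture tables completely", {
  tm <- read_spot_table(gelprot_example("table2_tm_con.csv"))
  pairs <- match_spots(dplyr::filter(tm, gel_id == "TM"),
                       dplyr::filter(tm, gel_id == "CON"))
  expect_equal(nrow(pairs), 48)
  expect_true(all(pairs$matched == "both"))
})

test_that("coordinate matching is mutual-nearest-neighbor within tolerance", {
  a <- tibble::tibble(spot_id = c("a1", "a2"), gel_id = "A",
                      pi = c(5, 7), mw_kda = c(30, 60),
                      ppm = c(100, 200))
  b <- dplyr::mutate(a, spot_id = c("b1", "b2"), gel_id = "B",
                     ppm = c(110, 190))
  perfect <- match_spots(a, b, by = "coordinates")
  expect_equal(sort(perfect$matched), c("both", "both"))
  expect_equal(perfect$control_ppm[perfect$spot_id == "a1"], 110)

  # displacement beyond tolerance leaves both sides unmatched
  b_far <- dplyr::mutate(b, pi = pi + c(0.5, 0))
  far <- match_spots(a, b_far, by = "coordinates", tol_pi = 0.15)
  expect_equal(far$matched[far$spot_id == "a1"], "case_only")
  expect_equal(far$matched[far$spot_id == "b1"], "control_only")
  expect_equal(far$control_ppm[far$spot_id == "a1"], 0)

  # empty inputs
  expect_equal(nrow(match_spots(a[0, ], b[0, ], by = "coordinates")), 0)
})

test_that("the two-fold rule classifies ratios with an inclusive boundary", {
  pairs <- tibble::tibble(
    spot_id = c("1203", "6105", "sub", "edge", "pa_up", "pa_down", "aa"),
    case_ppm = c(1526.9, 480.4, 150, 200, 50, 0, 0),
    control_ppm = c(345.8, 1075.2, 100, 100, 0, 70, 0)
  )
  d <- classify_twofold(pairs)
  expect_equal(d$direction[1:4], c("up", "down", "up", "up"))
  expect_equal(d$passes_twofold[1:4], c(TRUE, TRUE, FALSE, TRUE))
  # presence/absence policy
  expect_equal(d$ratio[5], Inf)
  expect_equal(d$direction[5:6], c("up", "down"))
  expect_true(all(d$passes_twofold[5:6]))
  expect_equal(d$call[5:7],
               c("presence_absence", "presence_absence", "absent_absent"))
  expect_false(d$passes_twofold[7])
  expect_equal(d$spot_id, pairs$spot_id)  # order preserved
  expect_error(classify_twofold(pairs, fold = 1), "> 1")
})

test_that("swapping case and control mirrors the classification", {
  set.seed(71)
  pairs <- tibble::tibble(
    spot_id = as.character(1:300),
    case_ppm = rlnorm(300, 6, 1.5),
    control_ppm = rlnorm(300, 6, 1.5)
  )
  fwd <- classify_twofold(pairs)
  rev <- classify_twofold(dplyr::rename(pairs, case_ppm = control_ppm,
                                        control_ppm = case_ppm))
  expect_identical(fwd$passes_twofold, rev$passes_twofold)
  expect_identical(fwd$direction == "up", rev$direction == "down")
})

test_that("overlap analysis keys on spot id and splits by direction", {
  a <- tibble::tibble(spot_id = c("1", "2", "3"),
                      direction = c("up", "down", "up"))
  b <- tibble::tibble(spot_id = c("2", "3", "4"),
                      direction = c("down", "down", "up"))
  ov <- overlap_analysis(a, b)
  expect_equal(ov$n_shared, 2)
  expect_equal(ov$n_same_direction, 1)
  expect_equal(ov$n_opposite_direction, 1)
  expect_equal(ov$n_shared, ov$n_same_direction + ov$n_opposite_direction)

  # disjoint sets
  empty <- overlap_analysis(a, tibble::tibble(spot_id = "9",
                                              direction = "up"))
  expect_equal(glance(empty),
               tibble::tibble(n_shared = 0L, n_same_direction = 0L,
                              n_opposite_direction = 0L))
  # reflexivity
  self <- overlap_analysis(a, a)
  expect_equal(self$n_shared, 3)
  expect_equal(self$n_opposite_direction, 0)
})

test_that("class proportions report counts and rounded percentages", {
  cat1 <- read_catalog()
  props <- class_proportions(cat1)
  expect_equal(sum(props$n), 97)
  expect_equal(sum(props$pct_display), 100, tolerance = 2)
  expect_lt(abs(sum(props$pct) - 100), 0.5)

  one <- class_proportions(tibble::tibble(functional_class = rep("x", 5)))
  expect_equal(one$pct, 100)
  expect_equal(nrow(class_proportions(tibble::tibble())), 0)
})
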