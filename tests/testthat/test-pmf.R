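# Peptide-mass-fingerprint search and identification criteria.

test_that("ppm error is a signed relative deviation", {
  expect_equal(ppm_error(1000.00, 1000.04), -39.9984, tolerance = 1e-4)
  expect_equal(ppm_error(1200.6, 1200.6), 0)
  expect_equal(ppm_error(1200.700, 1200.600), 83.29, tolerance = 1e-3)
  expect_error(ppm_error(100, 0), "> 0")
})

test_that("every fixture protein self-identifies against 50 decoys", {
  prot <- pmf_fixture_proteins()
  for (i in seq_len(nrow(prot))) {
    target <- prot[i, ]
    decoys <- shuffle_decoys(target, n = 50, seed = 101 + i)
    collection <- dplyr::bind_rows(target, decoys)
    peaks <- exact_peaks(target$sequence)
    res <- pmf_search(peaks, collection, tol_ppm = 50)
    expect_equal(res$accession[res$rank == 1], target$accession)
    expect_equal(res$n_matched[res$rank == 1], length(peaks))
    expect_gt(res$coverage[res$rank == 1], 0.3)
    expect_true(all(abs(tidy(res)$error_ppm) <= 50))
  }
})

test_that("a uniform +200 ppm shift defeats a 50 ppm tolerance", {
  prot <- pmf_fixture_proteins()
  peaks <- exact_peaks(prot$sequence[1]) * (1 + 200e-6)
  res <- pmf_search(peaks, prot, tol_ppm = 50)
  expect_true(all(res$n_matched == 0))
  expect_true(all(res$score == 0))
})

test_that("matches and score are non-decreasing in the tolerance", {
  prot <- pmf_fixture_proteins()
  set.seed(113)
  peaks <- exact_peaks(prot$sequence[1])
  peaks <- peaks * (1 + rnorm(length(peaks), 0, 30e-6))  # ~30 ppm jitter
  prev <- NULL
  for (tol in c(5, 15, 30, 60, 120)) {
    res <- pmf_search(peaks, prot[1, ], tol_ppm = tol)
    if (!is.null(prev)) {
      expect_gte(res$n_matched, prev$n_matched)
      expect_gte(res$score, prev$score - 1e-12)
    }
    prev <- res
  }
})

test_that("relabeling decoys permutes results without changing them", {
  prot <- pmf_fixture_proteins()
  decoys <- shuffle_decoys(prot[1, ], n = 20, seed = 131)
  peaks <- exact_peaks(prot$sequence[1])
  res1 <- pmf_search(peaks, dplyr::bind_rows(prot[1, ], decoys))
  set.seed(137)
  shuffled <- decoys[sample.int(nrow(decoys)), ]
  res2 <- pmf_search(peaks, dplyr::bind_rows(prot[1, ], shuffled))
  cols <- c("accession", "n_matched", "coverage", "score")
  expect_equal(dplyr::arrange(tibble::as_tibble(res1)[cols], accession),
               dplyr::arrange(tibble::as_tibble(res2)[cols], accession))
})

test_that("an empty peak list yields an empty warned result", {
  prot <- pmf_fixture_proteins()
  expect_warning(res <- pmf_search(numeric(0), prot), "empty")
  expect_equal(nrow(res), 0)
})

test_that("tandem-MS identification criteria follow the stated rule", {
  ev <- tibble::tibble(score = c(30, 40, 26), expect = c(0.1, 0.2, 0.5))
  expect_true(apply_msms_criteria(ev)$identified)
  # only two qualifying peptides
  ev2 <- tibble::tibble(score = c(30, 40), expect = c(0.1, 0.2))
  expect_false(apply_msms_criteria(ev2)$identified)
  # "over 25" is strict: a score of exactly 25 or below does not qualify
  ev3 <- tibble::tibble(score = c(30, 26, 24), expect = c(0.1, 0.1, 0.1))
  out3 <- apply_msms_criteria(ev3)
  expect_false(out3$identified)
  expect_equal(out3$n_qualifying, 2L)
  # expectation must be < 1
  ev4 <- tibble::tibble(score = c(30, 30, 30), expect = c(0.5, 0.5, 1))
  expect_false(apply_msms_criteria(ev4)$identified)
})

test_that("adding a qualifying peptide never revokes an identification", {
  set.seed(139)
  for (i in 1:50) {
    n <- sample(1:6, 1)
    ev <- tibble::tibble(score = runif(n, 0, 60), expect = runif(n, 0, 2))
    before <- apply_msms_criteria(ev)$identified
    more <- dplyr::bind_rows(ev, tibble::tibble(score = 40, expect = 0.01))
    after <- apply_msms_criteria(more)$identified
    expect_true(!before || after)
  }
})

test_that("catalog conformance is flagged without excluding rows", {
  cat1 <- check_identification_criteria(read_catalog())
  expect_equal(nrow(cat1), 97)
  expect_false(cat1$conforms[cat1$spot_no == 24])  # 2 peptides, score 12
  expect_true(cat1$conforms[cat1$spot_no == 4])    # 17 peptides, score 600
  expect_true(all(cat1$conforms[cat1$matched_peptides >= 3 &
                                  cat1$ms_score > 25]))
  expect_gt(sum(!cat1$conforms), 0)
})
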