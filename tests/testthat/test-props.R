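# Sequence physicochemistry: masses, isoelectric point, tryptic digestion.

test_that("peptide masses match brute-force summation over the mass table", {
  expect_equal(peptide_mass("G"), 75.03203, tolerance = 1e-7)
  expect_equal(peptide_mass("PEPTIDE"), 799.360, tolerance = 1e-3 / 799)
  set.seed(21)
  for (len in c(1, 5, 30)) {
    s <- random_seq(len)
    expect_equal(peptide_mass(s), oracle_mono_mass(s), tolerance = 1e-10)
  }
  # modification additivity
  expect_equal(
    peptide_mass("ACDK", carbamidomethyl = TRUE) - peptide_mass("ACDK"),
    57.02146
  )
  expect_equal(
    peptide_mass("AMDK", n_oxidation = 1) - peptide_mass("AMDK"),
    15.99491
  )
  expect_error(peptide_mass("AB1"), "non-amino-acid")
  expect_error(peptide_mass("ACDK", n_oxidation = 1), "methionine")
})

test_that("mass additivity: mass(a + b) = mass(a) + mass(b) - water", {
  set.seed(31)
  for (i in 1:20) {
    a <- random_seq(sample(3:25, 1))
    b <- random_seq(sample(3:25, 1))
    expect_equal(peptide_mass(paste0(a, b)),
                 peptide_mass(a) + peptide_mass(b) - 18.010565,
                 tolerance = 1e-9)
    expect_equal(peptide_mass(paste0(a, b), kind = "avg"),
                 peptide_mass(a, kind = "avg") +
                   peptide_mass(b, kind = "avg") - 18.01528,
                 tolerance = 1e-9)
  }
})

test_that("protein molecular weight reproduces database conventions", {
  myg <- read_fasta(gelprot_example("P02144.fasta"))
  mw <- protein_mw(myg$sequence)
  expect_equal(round(mw, 1), 17.2)
  expect_equal(round(protein_mw("GG"), 1), 0.1)
  expect_equal(protein_mw("GG") * 1000, 132.12, tolerance = 1e-4)
  expect_error(protein_mw(""), "empty")
  # data-frame interface adds columns
  out <- protein_mw(myg)
  expect_equal(out$mw_display, 17.2)
})

test_that("isoelectric point solves the Henderson-Hasselbalch charge model", {
  # no ionizable side chains: pI is the midpoint of the terminal pKas
  pka <- pka_table("emboss")
  expect_equal(isoelectric_point("AAA"),
               (pka[["Nterm"]] + pka[["Cterm"]]) / 2, tolerance = 0.01)
  # limit behavior for arbitrary sequences
  set.seed(41)
  for (i in 1:25) {
    s <- random_seq(sample(3:40, 1))
    expect_gt(net_charge(s, 0), 0)
    expect_lt(net_charge(s, 14), 0)
  }
})

test_that("bisection agrees with a dense grid search on random peptides", {
  set.seed(43)
  seqs <- vapply(1:100, function(i) random_seq(sample(5:40, 1)),
                 character(1))
  pi_bi <- isoelectric_point(seqs)
  pi_grid <- vapply(seqs, oracle_pi_grid, numeric(1))
  expect_lt(max(abs(pi_bi - pi_grid)), 0.02)
})

test_that("adding an arginine never decreases the isoelectric point", {
  set.seed(47)
  for (i in 1:25) {
    s <- random_seq(sample(4:30, 1))
    with_r <- paste0(s, "R")
    # brute-force charge-curve comparison: adding a base raises the curve,
    # so the zero crossing cannot move left
    grid <- seq(0, 14, by = 0.01)
    expect_true(all(net_charge(with_r, grid) >= net_charge(s, grid) - 1e-12))
    expect_gte(isoelectric_point(with_r) - isoelectric_point(s), -0.011)
  }
})

test_that("tryptic digestion applies the K/R-not-before-P rule", {
  d0 <- tryptic_digest("AKPIRGR", max_missed = 0)
  expect_equal(d0$peptide, c("AKPIR", "GR"))
  d1 <- tryptic_digest("AKPIRGR", max_missed = 1)
  expect_setequal(d1$peptide, c("AKPIR", "GR", "AKPIRGR"))
  expect_equal(d1$missed_cleavages[d1$peptide == "AKPIRGR"], 1L)
  # no cleavage site: single peptide
  expect_equal(tryptic_digest("MAAA")$peptide, "MAAA")
  # C-terminal K is not a site
  expect_equal(tryptic_digest("AAK", max_missed = 0)$peptide, "AAK")
})

test_that("digest partition and count identities hold on random sequences", {
  set.seed(53)
  for (i in 1:1000) {
    s <- random_seq(sample(2:40, 1))
    d <- tryptic_digest(s, max_missed = 2)
    zero <- d[d$missed_cleavages == 0, ]
    expect_identical(paste(zero$peptide[order(zero$start)], collapse = ""),
                     s)
    # count identity vs brute force, per missed-cleavage stratum
    oracle <- oracle_digest(s, 2)
    om <- vapply(oracle, function(x) x$missed, integer(1))
    for (m in 0:2) {
      expect_identical(sum(d$missed_cleavages == m), sum(om == m))
    }
    expect_setequal(
      paste(d$peptide, d$missed_cleavages),
      vapply(oracle, function(x) paste(x$peptide, x$missed), character(1))
    )
  }
})

test_that("digest variants expand oxidation and fix carbamidomethylation", {
  dp <- digest_peptides("ACMMKR", max_missed = 0, oxidation_max = 1)
  first <- dp[dp$peptide == "ACMMK", ]
  expect_equal(sort(first$n_oxidation), c(0L, 1L))
  expect_true(all(first$n_carbamidomethyl == 1L))
  expect_equal(
    first$mass[first$n_oxidation == 1] - first$mass[first$n_oxidation == 0],
    15.99491
  )
  dp2 <- digest_peptides("ACMMKR", max_missed = 0, oxidation_max = 2)
  expect_equal(sort(dp2$n_oxidation[dp2$peptide == "ACMMK"]), 0:2)
})
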