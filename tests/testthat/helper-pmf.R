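# Fixture collection for fingerprint tests: the packaged myoglobin plus
# two synthetic proteins generated under a fixed seed.
pmf_fixture_proteins <- function() {
  myg <- read_fasta(gelprot_example("P02144.fasta"))
  set.seed(97)
  tibble::tibble(
    accession = c(myg$accession, "SYN0001", "SYN0002"),
    sequence = c(myg$sequence, random_seq(180), random_seq(220))
  )
}

# Theoretical 0/1-missed tryptic peaks in a typical reflectron window.
exact_peaks <- function(seq) {
  dg <- digest_peptides(seq, max_missed = 1, oxidation_max = 0)
  sort(dg$mass[dg$mass > 500 & dg$mass < 3500])
}
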