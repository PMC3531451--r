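# Independent oracles used to compute expected values. These deliberately
# avoid the package's own code paths.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(len) paste(sample(AA20, len, replace = TRUE),
                                  collapse = "")

# Brute-force tryptic digestion: walk every position, record cleavage sites
# (after K/R unless followed by P), then join every run of 1..(m+1)
# consecutive fragments.
oracle_digest <- function(seq, max_missed) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  sites <- integer(0)
  for (i in seq_len(n - 1)) {
    if ((ch[i] == "K" || ch[i] == "R") && ch[i + 1] != "P") {
      sites <- c(sites, i)
    }
  }
  bounds <- c(0L, sites, n)
  frags <- character(length(bounds) - 1)
  for (k in seq_along(frags)) {
    frags[k] <- substr(seq, bounds[k] + 1L, bounds[k + 1L])
  }
  out <- list()
  for (m in 0:max_missed) {
    if (m >= length(frags)) break
    for (i in seq_len(length(frags) - m)) {
      out[[length(out) + 1L]] <- list(
        peptide = paste(frags[i:(i + m)], collapse = ""),
        missed = m
      )
    }
  }
  out
}

# Brute-force monoisotopic peptide mass by per-character summation against
# the shipped constant file (read directly, not through the package cache).
oracle_mono_mass <- function(seq) {
  tab <- utils::read.csv(gelprot_example("aa_masses.csv"))
  lut <- stats::setNames(tab$mono, tab$residue)
  sum(lut[strsplit(seq, "")[[1]]]) + 18.010565
}

# Dense grid search for the isoelectric point (step 0.001 pH).
oracle_pi_grid <- function(seq, step = 0.001) {
  grid <- seq(0, 14, by = step)
  q <- net_charge(seq, grid)
  grid[which.min(abs(q))]
}
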