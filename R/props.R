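# Sequence-derived physicochemical properties: peptide/protein mass,
# isoelectric point, and in-silico tryptic digestion. These underpin both
# the spot-position simulator and the peptide-mass-fingerprint layer.

#' Peptide mass from sequence
#'
#' Computes the (neutral) peptide mass as the sum of residue masses plus one
#' water, plus any modification deltas. Carbamidomethylation (+57.02146 Da
#' monoisotopic) applies to cysteines; oxidation (+15.9949 Da) to
#' methionines.
#'
#' @param seq Character vector of peptide sequences (one-letter codes).
#' @param kind `"mono"` (monoisotopic, default) or `"avg"` (average).
#' @param carbamidomethyl If `TRUE`, every cysteine carries the fixed
#'   carbamidomethyl modification.
#' @param n_oxidation Integer vector (recycled): number of oxidized
#'   methionines per peptide.
#' @return Numeric vector of masses in Da.
#' @export
#' @examples
#' peptide_mass("PEPTIDE")
#' peptide_mass("ACDK", carbamidomethyl = TRUE)
peptide_mass <- function(seq, kind = c("mono", "avg"),
                         carbamidomethyl = FALSE, n_oxidation = 0L) {
  kind <- arg_match(kind)
  seq <- check_residues(seq, "peptide")
  masses <- residue_masses(kind)
  cam <- if (kind == "mono") CARBAMIDOMETHYL_MONO else CARBAMIDOMETHYL_AVG
  oxi <- if (kind == "mono") OXIDATION_MONO else OXIDATION_AVG
  n_oxidation <- rep_len(as.integer(n_oxidation), length(seq))
  chars <- strsplit(seq, "")
  n_met <- map_int(chars, ~ sum(.x == "M"))
  if (any(n_oxidation > n_met)) {
    abort("n_oxidation exceeds the number of methionines in the peptide")
  }
  base <- map_dbl(chars, ~ sum(masses[.x])) + water_mass(kind)
  if (carbamidomethyl) {
    base <- base + cam * map_int(chars, ~ sum(.x == "C"))
  }
  base + oxi * n_oxidation
}

#' Theoretical protein molecular weight
#'
#' Average mass of the full (unprocessed) chain in kDa, i.e. with the
#' initiator methionine retained, matching the convention used for
#' database-reported protein masses.
#'
#' @param seq A protein sequence, or a data frame with a `sequence` column
#'   (as returned by [read_fasta()]).
#' @param digits Decimal places for the displayed value (`mw_display`).
#' @return For a character input, a numeric vector of masses in kDa. For a
#'   data frame input, the same frame with `theoretical_mw` (kDa, full
#'   precision) and `mw_display` (rounded) columns added.
#' @export
#' @examples
#' myg <- read_fasta(gelprot_example("P02144.fasta"))
#' protein_mw(myg$sequence)  # 17.18 kDa
protein_mw <- function(seq, digits = 1) {
  if (is.data.frame(seq)) {
    entries <- seq
    if (!"sequence" %in% names(entries)) {
      abort("data-frame input must have a 'sequence' column")
    }
    mw <- protein_mw(entries$sequence, digits = digits)
    return(mutate(entries,
      theoretical_mw = mw,
      mw_display = round(mw, digits)
    ))
  }
  if (any(!nzchar(seq))) abort("empty sequence")
  peptide_mass(seq, kind = "avg") / 1000
}

#' Net charge of a peptide or protein at a given pH
#'
#' Henderson-Hasselbalch occupancy model: the N-terminus and the basic side
#' chains (H, K, R) contribute `1 / (1 + 10^(pH - pKa))` positive charge
#' each; the C-terminus and the acidic side chains (C, D, E, Y) contribute
#' `-1 / (1 + 10^(pKa - pH))` each.
#'
#' @param seq A single sequence.
#' @param pH Numeric vector of pH values.
#' @param pka_set pKa convention, see [pka_table()].
#' @return Numeric vector of net charges, one per pH value.
#' @export
net_charge <- function(seq, pH, pka_set = c("emboss", "bjellqvist")) {
  seq <- check_residues(seq, "sequence")
  pka <- pka_table(pka_set)
  chars <- strsplit(seq, "")[[1]]
  counts <- table(factor(chars, levels = AA_ALPHABET))
  pos_groups <- c(Nterm = 1, H = unname(counts[["H"]]),
                  K = unname(counts[["K"]]), R = unname(counts[["R"]]))
  neg_groups <- c(Cterm = 1, C = unname(counts[["C"]]),
                  D = unname(counts[["D"]]), E = unname(counts[["E"]]),
                  Y = unname(counts[["Y"]]))
  map_dbl(pH, function(p) {
    pos <- sum(pos_groups / (1 + 10^(p - pka[names(pos_groups)])))
    neg <- sum(neg_groups / (1 + 10^(pka[names(neg_groups)] - p)))
    pos - neg
  })
}

#' Isoelectric point
#'
#' The pH at which the modeled net charge is zero, found by bisection on
#' \[0, 14\]. The net-charge curve is continuous and strictly decreasing,
#' positive at pH 0 and negative at pH 14, so the root exists and is unique.
#'
#' @param seq Character vector of sequences.
#' @param pka_set pKa convention, see [pka_table()].
#' @param tol Bisection tolerance in pH units.
#' @return Numeric vector of pI values.
#' @export
#' @examples
#' isoelectric_point("AAA")  # midpoint of the terminal pKa values
isoelectric_point <- function(seq, pka_set = c("emboss", "bjellqvist"),
                              tol = 0.01) {
  pka_set <- arg_match(pka_set)
  map_dbl(seq, function(s) {
    lo <- 0
    hi <- 14
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (net_charge(s, mid, pka_set) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P. Returns all
#' peptides carrying 0 to `max_missed` internal missed cleavages, annotated
#' with their position and missed-cleavage count. A C-terminal K/R is not a
#' cleavage site (there is nothing to cleave); the initiator methionine is
#' not removed.
#'
#' @param seq A single protein sequence.
#' @param max_missed Maximum number of internal missed cleavages.
#' @return A tibble with columns `peptide`, `start`, `end`,
#'   `missed_cleavages`, ordered by `start` then `missed_cleavages`.
#' @export
#' @examples
#' tryptic_digest("AKPIRGR", max_missed = 1)
tryptic_digest <- function(seq, max_missed = 1) {
  stopifnot(length(seq) == 1, max_missed >= 0)
  seq <- check_residues(seq, "sequence")
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n == 0) abort("empty sequence")
  # Internal cleavage sites: position i such that we cut between i and i+1.
  sites <- which(chars[-n] %in% c("K", "R") & chars[-1] != "P")
  bounds <- c(0L, sites, n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  n_frag <- length(starts)
  out <- vector("list", 0L)
  for (m in 0:min(max_missed, n_frag - 1L)) {
    i <- seq_len(n_frag - m)
    out[[m + 1L]] <- tibble(
      peptide = substring(seq, starts[i], ends[i + m]),
      start = starts[i],
      end = ends[i + m],
      missed_cleavages = m
    )
  }
  arrange(bind_rows(out), .data$start, .data$missed_cleavages)
}

#' Digest a protein into modified peptide ions
#'
#' Runs [tryptic_digest()] and expands each peptide into its modification
#' variants: fixed carbamidomethylation of every cysteine (optional) and 0
#' to `oxidation_max` oxidized methionines, then computes the neutral mass
#' of each variant.
#'
#' @inheritParams tryptic_digest
#' @param carbamidomethyl Apply fixed carbamidomethyl-C (default `TRUE`,
#'   the standard alkylation for in-gel digests).
#' @param oxidation_max Maximum oxidized methionines per peptide (default 1).
#' @param kind Mass kind, `"mono"` or `"avg"`.
#' @return A tibble with `peptide`, `start`, `end`, `missed_cleavages`,
#'   `n_carbamidomethyl`, `n_oxidation`, `mass`.
#' @export
digest_peptides <- function(seq, max_missed = 1, carbamidomethyl = TRUE,
                            oxidation_max = 1, kind = c("mono", "avg")) {
  kind <- arg_match(kind)
  pep <- tryptic_digest(seq, max_missed)
  chars <- strsplit(pep$peptide, "")
  pep$n_carbamidomethyl <- if (carbamidomethyl) {
    map_int(chars, ~ sum(.x == "C"))
  } else {
    0L
  }
  n_met <- map_int(chars, ~ sum(.x == "M"))
  pep <- tidyr::uncount(
    mutate(pep, .n = pmin(n_met, oxidation_max) + 1L),
    .data$.n, .id = ".variant"
  )
  pep$n_oxidation <- pep$.variant - 1L
  pep$.variant <- NULL
  pep$mass <- peptide_mass(pep$peptide, kind = kind,
                           carbamidomethyl = carbamidomethyl,
                           n_oxidation = pep$n_oxidation)
  as_tibble(pep)
}
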