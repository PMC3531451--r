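# Peptide-mass-fingerprint search and tandem-MS identification criteria.
# The search digests every candidate in silico (trypsin, bounded missed
# cleavages, fixed carbamidomethyl-C, variable oxidation-M), matches each
# observed peak to at most one theoretical peptide within a ppm tolerance,
# and ranks candidates by a MOWSE-style rarity score. The score is a
# repository-defined ranking statistic; it is not comparable to scores
# printed by commercial search engines.

#' Relative mass error in parts per million
#'
#' `(observed - theoretical) / theoretical * 1e6`.
#'
#' @param observed,theoretical Masses in Da; `theoretical` must be > 0.
#' @return Signed error in ppm.
#' @export
#' @examples
#' ppm_error(1000.00, 1000.04)  # -40 ppm
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) abort("theoretical mass must be > 0")
  (observed - theoretical) / theoretical * 1e6
}

#' Peptide-mass-fingerprint search
#'
#' Searches an observed peak list against a collection of protein
#' sequences. Each candidate is digested with [digest_peptides()]; each
#' observed peak is then matched to at most one theoretical peptide mass of
#' the candidate within `tol_ppm` (and each theoretical peptide consumed at
#' most once): candidate pairs are taken in order of absolute mass error,
#' ties broken toward the lower peptide mass. Candidates are ranked by
#' score (descending), ties broken by matched-peak count and then
#' accession.
#'
#' The score is MOWSE-style: every matched peptide contributes
#' `log10(1 / f)` where `f` is the relative frequency of theoretical
#' peptides (across the whole search collection) in that peptide's 100 Da
#' mass bin — matching a rare (heavy) peptide is worth more than matching a
#' ubiquitous light one. Both the matched-peak count and the score are
#' non-decreasing in the tolerance.
#'
#' @param peaks A peak list tibble ([read_peaklist()]) or numeric vector of
#'   m/z values in Da.
#' @param proteins A sequence collection ([read_fasta()]): `accession`,
#'   `sequence`.
#' @param tol_ppm Mass tolerance in ppm (default 50).
#' @param max_missed Maximum missed cleavages (default 1).
#' @param carbamidomethyl Fixed carbamidomethylation of cysteine (default
#'   `TRUE`).
#' @param oxidation_max Maximum variable methionine oxidations per peptide
#'   (default 1).
#' @param kind Mass kind (default `"mono"`, the reflectron-MALDI
#'   convention).
#' @param bin_width MOWSE mass-bin width in Da (default 100).
#' @return A `gelprot_pmf` tibble ranked by score: `rank`, `accession`,
#'   `n_matched`, `n_observed`, `coverage`, `score`, and a `matches`
#'   list-column of per-peak match tables (`mz`, `peptide`, `mass`,
#'   `error_ppm`).
#' @export
pmf_search <- function(peaks, proteins, tol_ppm = 50, max_missed = 1,
                       carbamidomethyl = TRUE, oxidation_max = 1,
                       kind = c("mono", "avg"), bin_width = 100) {
  kind <- arg_match(kind)
  mz <- if (is.data.frame(peaks)) peaks$mz else as.numeric(peaks)
  if (nrow(proteins) == 0 || !all(nzchar(proteins$sequence))) {
    abort("pmf_search needs a non-empty protein collection with sequences")
  }
  if (length(mz) == 0) {
    warn("empty peak list: returning empty result")
    return(structure(
      tibble(rank = integer(0), accession = character(0),
             n_matched = integer(0), n_observed = integer(0),
             coverage = numeric(0), score = numeric(0), matches = list()),
      class = c("gelprot_pmf", class(tibble()))
    ))
  }
  digests <- map(proteins$sequence, digest_peptides,
                 max_missed = max_missed,
                 carbamidomethyl = carbamidomethyl,
                 oxidation_max = oxidation_max, kind = kind)
  # Collection-wide mass-bin frequencies for the rarity score.
  all_masses <- unlist(map(digests, "mass"))
  bins <- table(floor(all_masses / bin_width))
  bin_freq <- as.numeric(bins) / length(all_masses)
  names(bin_freq) <- names(bins)
  results <- map(seq_len(nrow(proteins)), function(i) {
    dg <- digests[[i]]
    m <- match_peaks(mz, dg$mass, tol_ppm)
    obs <- mz[m$peak]
    theo <- dg$mass[m$peptide]
    matched <- tibble(
      mz = obs,
      peptide = dg$peptide[m$peptide],
      mass = theo,
      error_ppm = if (length(obs)) ppm_error(obs, theo) else numeric(0)
    )
    f <- bin_freq[as.character(floor(matched$mass / bin_width))]
    f <- pmax(as.numeric(f), 1 / length(all_masses))
    cov_pos <- rep(FALSE, nchar(proteins$sequence[[i]]))
    if (nrow(matched) > 0) {
      for (j in m$peptide) cov_pos[dg$start[j]:dg$end[j]] <- TRUE
    }
    tibble(
      accession = proteins$accession[[i]],
      n_matched = nrow(matched),
      n_observed = length(mz),
      coverage = mean(cov_pos),
      score = sum(log10(1 / f)),
      matches = list(matched)
    )
  }) %>% list_rbind()
  out <- results %>%
    arrange(desc(.data$score), desc(.data$n_matched), .data$accession) %>%
    mutate(rank = row_number()) %>%
    select("rank", dplyr::everything())
  attr(out, "params") <- list(
    tol_ppm = tol_ppm, max_missed = max_missed,
    carbamidomethyl = carbamidomethyl, oxidation_max = oxidation_max,
    kind = kind, bin_width = bin_width
  )
  class(out) <- c("gelprot_pmf", class(tibble()))
  out
}

# Greedy one-to-one assignment of observed peaks to theoretical masses
# within tol_ppm: candidate pairs in order of |ppm error|, ties toward the
# lower peptide mass; each peak and each peptide used at most once.
match_peaks <- function(mz, masses, tol_ppm) {
  if (length(mz) == 0 || length(masses) == 0) {
    return(list(peak = integer(0), peptide = integer(0)))
  }
  err <- outer(mz, masses, ppm_error)
  cand <- which(abs(err) <= tol_ppm, arr.ind = TRUE)
  if (nrow(cand) == 0) return(list(peak = integer(0), peptide = integer(0)))
  ord <- order(abs(err[cand]), masses[cand[, 2]])
  cand <- cand[ord, , drop = FALSE]
  used_peak <- rep(FALSE, length(mz))
  used_pep <- rep(FALSE, length(masses))
  keep_peak <- integer(0)
  keep_pep <- integer(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]
    j <- cand[k, 2]
    if (used_peak[i] || used_pep[j]) next
    used_peak[i] <- TRUE
    used_pep[j] <- TRUE
    keep_peak <- c(keep_peak, i)
    keep_pep <- c(keep_pep, j)
  }
  list(peak = keep_peak, peptide = keep_pep)
}

#' Generate residue-shuffled decoy sequences
#'
#' Shuffles the residues of each input sequence `n` times, preserving
#' composition (the standard null for fingerprint ranking tests).
#'
#' @param proteins A sequence collection (`accession`, `sequence`).
#' @param n Decoys per input sequence.
#' @param seed Integer seed.
#' @return A tibble of decoys with accessions `DECOY_<accession>_<i>`.
#' @export
shuffle_decoys <- function(proteins, n = 50, seed = 1) {
  set.seed(seed)
  out <- map(seq_len(nrow(proteins)), function(i) {
    chars <- strsplit(proteins$sequence[[i]], "")[[1]]
    tibble(
      accession = sprintf("DECOY_%s_%02d", proteins$accession[[i]],
                          seq_len(n)),
      sequence = map_chr(seq_len(n),
                         ~ paste(sample(chars), collapse = ""))
    )
  })
  list_rbind(out)
}

#' Apply tandem-MS identification criteria
#'
#' A protein is considered identified when at least `min_peptides` of its
#' peptides carry a search score strictly greater than `min_score` and an
#' expectation value strictly below `max_expect`. The evidence table holds
#' one row per peptide-spectrum match with `score` and `expect` columns;
#' with an `accession` column, the rule is applied per accession.
#'
#' @param evidence A tibble of peptide records (`peptide` optional,
#'   `score`, `expect`, optionally `accession`).
#' @param min_peptides,min_score,max_expect The criteria (defaults 3, 25,
#'   1).
#' @return One row per protein: `n_peptides`, `n_qualifying`, `identified`,
#'   and a `qualifying` list-column naming the qualifying peptide rows.
#' @export
#' @examples
#' ev <- tibble::tibble(score = c(30, 40, 26), expect = c(0.1, 0.2, 0.5))
#' apply_msms_criteria(ev)$identified  # TRUE
apply_msms_criteria <- function(evidence, min_peptides = 3, min_score = 25,
                                max_expect = 1) {
  stopifnot(all(c("score", "expect") %in% names(evidence)))
  if (any(evidence$expect < 0)) abort("expectation values must be >= 0")
  grouping <- if ("accession" %in% names(evidence)) "accession" else character(0)
  evidence %>%
    mutate(.qualifies = .data$score > min_score &
             .data$expect < max_expect) %>%
    group_by(across(dplyr::all_of(grouping))) %>%
    summarise(
      n_peptides = n(),
      n_qualifying = sum(.data$.qualifies),
      identified = sum(.data$.qualifies) >= min_peptides,
      qualifying = list(filter(dplyr::pick(dplyr::everything()),
                               .data$.qualifies) %>%
                          select(-dplyr::any_of(".qualifies"))),
      .groups = "drop"
    )
}

#' Flag catalog rows against the stated identification criteria
#'
#' Checks each row of an identified-protein catalog against the
#' identification rule (at least `min_peptides` matched peptides and a
#' search score above `min_score`) and adds a `conforms` flag. Rows that
#' fail are flagged, never removed: a catalog can legitimately contain
#' single-peptide identifications accepted on other grounds, and these
#' should remain visible.
#'
#' @param catalog A catalog tibble ([read_catalog()]) with
#'   `matched_peptides` and `ms_score`.
#' @param min_peptides,min_score The criteria (defaults 3 and 25).
#' @return The catalog with a logical `conforms` column.
#' @export
check_identification_criteria <- function(catalog, min_peptides = 3,
                                          min_score = 25) {
  stopifnot(all(c("matched_peptides", "ms_score") %in% names(catalog)))
  mutate(catalog,
         conforms = .data$matched_peptides >= min_peptides &
           .data$ms_score > min_score)
}
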