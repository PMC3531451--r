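# Physical constants used by the mass and pI layer. The residue masses and
# pKa values ship as documented CSV files under inst/extdata so that tests
# and independent oracles read the same numbers as the implementation.

.gelprot_cache <- new.env(parent = emptyenv())

# Monoisotopic mass of water (Da); average counterpart.
WATER_MONO <- 18.010565
WATER_AVG <- 18.01528

# Modification deltas (Da): carbamidomethylation of Cys, oxidation of Met.
CARBAMIDOMETHYL_MONO <- 57.02146
CARBAMIDOMETHYL_AVG <- 57.0513
OXIDATION_MONO <- 15.99491
OXIDATION_AVG <- 15.9994

AA_ALPHABET <- c(
  "A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
  "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y"
)

#' Amino-acid residue mass table
#'
#' Monoisotopic and average residue masses (Da) for the 20 standard amino
#' acids, as shipped in `aa_masses.csv`.
#'
#' @return A tibble with columns `residue`, `mono`, `avg`.
#' @export
aa_mass_table <- function() {
  if (is.null(.gelprot_cache$aa)) {
    .gelprot_cache$aa <- readr::read_csv(
      gelprot_example("aa_masses.csv"),
      col_types = readr::cols(
        residue = readr::col_character(),
        mono = readr::col_double(),
        avg = readr::col_double()
      )
    )
  }
  .gelprot_cache$aa
}

#' Ionizable-group pKa table
#'
#' pKa values for the protein termini and the ionizable side chains
#' (C, D, E, H, K, R, Y) under the named convention. Two conventions ship
#' with the package: `"emboss"` (default throughout) and `"bjellqvist"`.
#'
#' @param set `"emboss"` or `"bjellqvist"`.
#' @return A named numeric vector with elements `Nterm`, `Cterm`, `C`, `D`,
#'   `E`, `H`, `K`, `R`, `Y`.
#' @export
pka_table <- function(set = c("emboss", "bjellqvist")) {
  set <- arg_match(set)
  if (is.null(.gelprot_cache$pka)) {
    .gelprot_cache$pka <- readr::read_csv(
      gelprot_example("pka_sets.csv"),
      col_types = readr::cols(
        group = readr::col_character(),
        .default = readr::col_double()
      )
    )
  }
  tab <- .gelprot_cache$pka
  setNames(tab[[set]], tab$group)
}

# Residue mass lookup as a named vector for fast indexing.
residue_masses <- function(kind = c("mono", "avg")) {
  kind <- arg_match(kind)
  tab <- aa_mass_table()
  setNames(tab[[kind]], tab$residue)
}

water_mass <- function(kind = c("mono", "avg")) {
  kind <- arg_match(kind)
  if (kind == "mono") WATER_MONO else WATER_AVG
}

# Checks a vector of sequences for non-standard residues; errors naming the
# offending symbols and the first offending position.
check_residues <- function(seqs, what = "sequence") {
  bad <- lapply(strsplit(toupper(seqs), ""), function(ch) {
    which(!ch %in% AA_ALPHABET)
  })
  hit <- which(lengths(bad) > 0)
  if (length(hit) > 0) {
    i <- hit[[1]]
    pos <- bad[[i]][[1]]
    sym <- substr(toupper(seqs[[i]]), pos, pos)
    offenders <- unique(unlist(lapply(hit, function(j) {
      strsplit(toupper(seqs[[j]]), "")[[1]][bad[[j]]]
    })))
    abort(paste0(
      "invalid ", what, ": non-amino-acid symbol(s) ",
      paste0("'", offenders, "'", collapse = ", "),
      " (first at position ", pos, " of element ", i, ")"
    ))
  }
  invisible(toupper(seqs))
}
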