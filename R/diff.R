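# The core comparison: per-gel ppm normalization, cross-gel spot matching,
# two-fold differential classification, overlap/direction analysis between
# two case-control comparisons, and functional-class proportions.

#' Normalize spot intensities to parts per million
#'
#' Each spot's IOD is divided by the summed IOD of all spots on the same
#' gel and scaled to parts per million, correcting for gel-to-gel
#' differences in total stain intensity: `ppm_i = iod_i / sum_j(iod_j) *
#' 1e6` within each `gel_id`. The result is invariant under any global
#' scaling of a gel's intensities.
#'
#' @param x A spot table with `iod` populated.
#' @return The table with a `ppm` column; per gel, `ppm` sums to 1e6.
#' @export
normalize_ppm <- function(x) {
  validate_spot_table(x)
  if (!"iod" %in% names(x)) abort("normalize_ppm needs an 'iod' column")
  if (anyNA(x$iod)) abort("normalize_ppm: 'iod' contains missing values")
  totals <- x %>%
    group_by(.data$gel_id) %>%
    summarise(total = sum(.data$iod), .groups = "drop")
  if (any(totals$total <= 0)) {
    abort(paste0("cannot normalize gel(s) with zero total IOD: ",
                 paste(totals$gel_id[totals$total <= 0], collapse = ", ")))
  }
  x %>%
    group_by(.data$gel_id) %>%
    mutate(ppm = .data$iod / sum(.data$iod) * 1e6) %>%
    ungroup()
}

#' Match spots between two gels
#'
#' Pairs the spots of a case gel with those of a control gel. When both
#' tables share spot identifiers (the fixture situation, where matching was
#' already performed upstream), pairing is by `spot_id`. Otherwise pairing
#' is mutual-nearest-neighbor in (pI, log10 MW) space within the stated
#' tolerances. Spots present on only one side are reported with ppm 0 on
#' the missing side (a presence/absence event), never dropped.
#'
#' @param case,control Spot tables carrying `ppm` (see [normalize_ppm()]).
#' @param by `"auto"` (ids when shared, else coordinates), `"spot_id"`, or
#'   `"coordinates"`.
#' @param tol_pi,tol_log10mw Coordinate-matching tolerances (pH units,
#'   log10 kDa).
#' @return A paired tibble: `spot_id`, `protein` (when available),
#'   `case_ppm`, `control_ppm`, `matched` (`"both"`, `"case_only"`,
#'   `"control_only"`), and coordinates of the case side where known.
#' @export
match_spots <- function(case, control,
                        by = c("auto", "spot_id", "coordinates"),
                        tol_pi = 0.15, tol_log10mw = 0.05) {
  by <- arg_match(by)
  if (by == "auto") {
    shared <- length(intersect(case$spot_id, control$spot_id)) > 0
    by <- if (shared) "spot_id" else "coordinates"
  }
  if (by == "spot_id") {
    keep <- intersect(c("spot_id", "protein", "pi", "mw_kda", "ppm"),
                      names(case))
    keep_ctrl <- intersect(c("spot_id", "protein", "pi", "mw_kda", "ppm"),
                           names(control))
    pairs <- full_join(
      select(case, dplyr::all_of(keep)),
      select(control, dplyr::all_of(keep_ctrl)),
      by = "spot_id", suffix = c("", ".control")
    )
    out <- pairs %>%
      mutate(
        case_ppm = if_else(is.na(.data$ppm), 0, .data$ppm),
        control_ppm = if_else(is.na(.data$ppm.control), 0,
                              .data$ppm.control),
        matched = dplyr::case_when(
          is.na(.data$ppm) ~ "control_only",
          is.na(.data$ppm.control) ~ "case_only",
          TRUE ~ "both"
        )
      )
    if ("protein.control" %in% names(out)) {
      out <- mutate(out, protein = dplyr::coalesce(.data$protein,
                                                   .data$protein.control))
    }
    return(select(out, dplyr::any_of(c(
      "spot_id", "protein", "pi", "mw_kda", "case_ppm", "control_ppm",
      "matched"
    ))))
  }
  # Coordinate mode: mutual nearest neighbor in scaled (pI, log10 MW).
  for (tb in list(case, control)) {
    if (!all(c("pi", "mw_kda", "ppm") %in% names(tb))) {
      abort("coordinate matching needs 'pi', 'mw_kda' and 'ppm' columns")
    }
  }
  if (nrow(case) == 0 || nrow(control) == 0) {
    empty_side <- function(tb, side) {
      tibble(
        spot_id = tb$spot_id,
        protein = if ("protein" %in% names(tb)) tb$protein else NA_character_,
        pi = tb$pi, mw_kda = tb$mw_kda,
        case_ppm = if (side == "case") tb$ppm else 0,
        control_ppm = if (side == "control") tb$ppm else 0,
        matched = paste0(side, "_only")
      )
    }
    return(bind_rows(empty_side(case, "case"), empty_side(control, "control")))
  }
  d_pi <- outer(case$pi, control$pi, "-") / tol_pi
  d_mw <- outer(log10(case$mw_kda), log10(control$mw_kda), "-") / tol_log10mw
  d <- sqrt(d_pi^2 + d_mw^2)
  d[d > 1] <- Inf
  nn_case <- apply(d, 1, which.min)
  nn_ctrl <- apply(d, 2, which.min)
  i <- seq_len(nrow(case))
  mutual <- is.finite(d[cbind(i, nn_case)]) & nn_ctrl[nn_case] == i
  pair_idx <- tibble(ci = i[mutual], ki = nn_case[mutual])
  get_protein <- function(tb, idx) {
    if ("protein" %in% names(tb)) tb$protein[idx] else NA_character_
  }
  matched_tbl <- tibble(
    spot_id = case$spot_id[pair_idx$ci],
    protein = get_protein(case, pair_idx$ci),
    pi = case$pi[pair_idx$ci],
    mw_kda = case$mw_kda[pair_idx$ci],
    case_ppm = case$ppm[pair_idx$ci],
    control_ppm = control$ppm[pair_idx$ki],
    matched = "both"
  )
  case_only <- tibble(
    spot_id = case$spot_id[!mutual],
    protein = get_protein(case, which(!mutual)),
    pi = case$pi[!mutual],
    mw_kda = case$mw_kda[!mutual],
    case_ppm = case$ppm[!mutual],
    control_ppm = 0,
    matched = "case_only"
  )
  un_ctrl <- setdiff(seq_len(nrow(control)), pair_idx$ki)
  control_only <- tibble(
    spot_id = control$spot_id[un_ctrl],
    protein = get_protein(control, un_ctrl),
    pi = control$pi[un_ctrl],
    mw_kda = control$mw_kda[un_ctrl],
    case_ppm = 0,
    control_ppm = control$ppm[un_ctrl],
    matched = "control_only"
  )
  bind_rows(matched_tbl, case_only, control_only)
}

#' Classify matched spots under a fold-change rule
#'
#' For each pair, computes `ratio = case_ppm / control_ppm`, the direction
#' (`up` when ratio > 1, `down` when < 1, `unchanged` at exactly 1), and
#' whether the pair passes the rule "at least `fold`-fold higher or lower"
#' — inclusive, so a ratio of exactly `fold` or `1/fold` passes. A spot
#' absent from the control gel (control ppm 0, case ppm > 0) has ratio
#' `Inf`, direction up, and passes; the converse has ratio 0, direction
#' down, and passes; both are flagged as presence/absence calls. Pairs
#' absent on both sides are flagged `absent_absent` and never pass. Input
#' order is preserved.
#'
#' @param pairs A paired table from [match_spots()] (or any data frame with
#'   `case_ppm` and `control_ppm`).
#' @param fold Fold threshold (> 1; default 2).
#' @return The input with `ratio`, `direction`, `passes_twofold`, and
#'   `call` (`"quantified"`, `"presence_absence"`, `"absent_absent"`)
#'   columns, classed `gelprot_diff`.
#' @export
#' @examples
#' tm <- read_spot_table(gelprot_example("table2_tm_con.csv"))
#' pairs <- match_spots(
#'   dplyr::filter(tm, gel_id == "TM"),
#'   dplyr::filter(tm, gel_id == "CON")
#' )
#' diff <- classify_twofold(pairs)
#' sum(diff$passes_twofold)  # 48
classify_twofold <- function(pairs, fold = 2) {
  stopifnot(all(c("case_ppm", "control_ppm") %in% names(pairs)))
  if (fold <= 1) abort("fold threshold must be > 1")
  out <- pairs %>%
    mutate(
      ratio = .data$case_ppm / .data$control_ppm,
      ratio = if_else(.data$control_ppm == 0 & .data$case_ppm > 0,
                      Inf, .data$ratio),
      ratio = if_else(.data$control_ppm == 0 & .data$case_ppm == 0,
                      NA_real_, .data$ratio),
      direction = dplyr::case_when(
        is.na(.data$ratio) ~ "unchanged",
        .data$ratio > 1 ~ "up",
        .data$ratio < 1 ~ "down",
        TRUE ~ "unchanged"
      ),
      call = dplyr::case_when(
        .data$case_ppm == 0 & .data$control_ppm == 0 ~ "absent_absent",
        .data$case_ppm == 0 | .data$control_ppm == 0 ~ "presence_absence",
        TRUE ~ "quantified"
      ),
      passes_twofold = !is.na(.data$ratio) &
        (.data$ratio >= fold | .data$ratio <= 1 / fold)
    )
  attr(out, "fold") <- fold
  class(out) <- c("gelprot_diff", class(tibble()))
  out
}

#' Extract the passing set of a differential classification
#'
#' @param diff A [classify_twofold()] result.
#' @return Rows with `passes_twofold` `TRUE`.
#' @export
differential_spots <- function(diff) {
  stopifnot("passes_twofold" %in% names(diff))
  filter(diff, .data$passes_twofold)
}

#' Overlap between two differential comparisons
#'
#' Given the passing sets of two case-vs-control comparisons (keyed by spot
#' identifier, not by protein accession, since the same protein can appear
#' as distinct isoform spots), reports the shared spots and whether each
#' changed in the same direction in both comparisons.
#'
#' @param a,b Passing differential records (see [differential_spots()]),
#'   each with `spot_id` and `direction`.
#' @return A `gelprot_overlap` list: `shared` (tibble of spot_id,
#'   direction_a, direction_b, same_direction), `n_shared`,
#'   `n_same_direction`, `n_opposite_direction`.
#' @export
#' @examples
#' \donttest{
#' run_fixture_analysis()$overlap
#' }
overlap_analysis <- function(a, b) {
  for (tb in list(a, b)) {
    stopifnot(all(c("spot_id", "direction") %in% names(tb)))
  }
  shared <- inner_join(
    select(a, "spot_id", direction_a = "direction",
           dplyr::any_of("protein")),
    select(b, "spot_id", direction_b = "direction"),
    by = "spot_id"
  ) %>%
    mutate(same_direction = .data$direction_a == .data$direction_b) %>%
    arrange(.data$spot_id)
  structure(
    list(
      shared = shared,
      n_shared = nrow(shared),
      n_same_direction = sum(shared$same_direction),
      n_opposite_direction = sum(!shared$same_direction)
    ),
    class = "gelprot_overlap"
  )
}

#' @export
print.gelprot_overlap <- function(x, ...) {
  cat("<overlap> shared:", x$n_shared, "| same direction:",
      x$n_same_direction, "| opposite:", x$n_opposite_direction, "\n")
  if (x$n_opposite_direction > 0) {
    opp <- filter(x$shared, !.data$same_direction)
    cat("  opposite spots:", paste(opp$spot_id, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Functional-class proportions of a protein catalog
#'
#' Counts catalog entries per functional class and reports each class as a
#' percentage of the total, kept to 3 significant figures (`pct`) plus an
#' integer display value (`pct_display`).
#'
#' @param entries A catalog data frame with a `functional_class` column
#'   (e.g. `read_catalog()`).
#' @return A tibble (`functional_class`, `n`, `pct`, `pct_display`), in
#'   decreasing order of `n`.
#' @export
class_proportions <- function(entries) {
  if (nrow(entries) == 0) {
    return(tibble(functional_class = character(0), n = integer(0),
                  pct = numeric(0), pct_display = integer(0)))
  }
  stopifnot("functional_class" %in% names(entries))
  entries %>%
    count(.data$functional_class, name = "n") %>%
    mutate(
      pct = signif(.data$n / sum(.data$n) * 100, 3),
      pct_display = as.integer(round(.data$pct))
    ) %>%
    arrange(desc(.data$n))
}

#' Read the identified-protein catalog
#'
#' Loads a protein catalog CSV (one row per identified spot: spot number,
#' protein name, molecular function, accession, database molecular weight
#' and isoelectric point, matched-peptide count and search-engine score,
#' functional class). The packaged `table1_catalog.csv` holds the 97
#' identified spots of the microdialysate study.
#'
#' @param path CSV path (defaults to the packaged catalog).
#' @return A tibble with one row per catalog spot.
#' @export
read_catalog <- function(path = gelprot_example("table1_catalog.csv")) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      spot_no = readr::col_integer(),
      protein = readr::col_character(),
      molecular_function = readr::col_character(),
      accession = readr::col_character(),
      mw_kda = readr::col_double(),
      pi = readr::col_double(),
      matched_peptides = readr::col_integer(),
      ms_score = readr::col_double(),
      functional_class = readr::col_character()
    )
  )
}
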