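# broom-style tidiers for the non-tabular result objects.

#' Tidy an overlap analysis
#'
#' @param x A `gelprot_overlap` from [overlap_analysis()].
#' @param ... Unused.
#' @return The per-spot direction-pair tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.gelprot_overlap <- function(x, ...) x$shared

#' @rdname tidy.gelprot_overlap
#' @export
#' @exportS3Method generics::glance
glance.gelprot_overlap <- function(x, ...) {
  tibble(
    n_shared = x$n_shared,
    n_same_direction = x$n_same_direction,
    n_opposite_direction = x$n_opposite_direction
  )
}

#' Tidy a fixture report
#'
#' @param x A `gelprot_report` from [run_fixture_analysis()].
#' @param ... Unused.
#' @return `tidy()`: the two classified comparisons stacked, with a
#'   `comparison` column. `glance()`: the headline counts as one row.
#' @export
#' @exportS3Method generics::tidy
tidy.gelprot_report <- function(x, ...) {
  bind_rows(
    mutate(as_tibble(x$tm), comparison = "case_a_vs_control"),
    mutate(as_tibble(x$cwp), comparison = "case_b_vs_control")
  )
}

#' @rdname tidy.gelprot_report
#' @export
#' @exportS3Method generics::glance
glance.gelprot_report <- function(x, ...) {
  as_tibble(as.list(x$counts))
}

#' Tidy a synthetic pipeline run
#'
#' @param x A `gelprot_run` from [run_pipeline()].
#' @param ... Unused.
#' @return `tidy()`: the per-truth-spot evaluation table. `glance()`: the
#'   one-row metrics tibble.
#' @export
#' @exportS3Method generics::tidy
tidy.gelprot_run <- function(x, ...) as_tibble(x$truth_eval)

#' @rdname tidy.gelprot_run
#' @export
#' @exportS3Method generics::glance
glance.gelprot_run <- function(x, ...) x$metrics

#' Tidy a fingerprint search
#'
#' @param x A `gelprot_pmf` from [pmf_search()].
#' @param ... Unused.
#' @return `tidy()`: per-candidate matched peaks, unnested. `glance()`:
#'   one row with the search parameters and the top hit.
#' @export
#' @exportS3Method generics::tidy
tidy.gelprot_pmf <- function(x, ...) {
  x %>%
    as_tibble() %>%
    select("rank", "accession", "matches") %>%
    tidyr::unnest("matches")
}

#' @rdname tidy.gelprot_pmf
#' @export
#' @exportS3Method generics::glance
glance.gelprot_pmf <- function(x, ...) {
  p <- attr(x, "params")
  top <- filter(as_tibble(x), .data$rank == 1)
  tibble(
    top_accession = top$accession[1],
    top_score = top$score[1],
    top_n_matched = top$n_matched[1],
    n_candidates = nrow(x),
    tol_ppm = p$tol_ppm,
    max_missed = p$max_missed
  )
}
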