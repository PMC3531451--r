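# End-to-end orchestration: the fixture analysis that reproduces the
# published differential tables, and the simulate -> quantify -> normalize
# -> match -> classify -> evaluate pipeline on synthetic scenes.

#' Reproduce the packaged case-control analysis
#'
#' Runs the whole differential procedure on the packaged fixtures: the
#' TM-vs-CON and CWP-vs-CON differential spot tables and the 97-spot
#' identified-protein catalog. (TM: chronic trapezius myalgia; CWP: chronic
#' widespread pain; CON: healthy controls — the three pooled-dialysate
#' gels.) Classifies both comparisons under the inclusive two-fold rule,
#' intersects their passing sets by spot id, and tabulates
#' functional-class proportions and identification-criteria conformance of
#' the catalog.
#'
#' @param fold Fold threshold (default 2).
#' @return A `gelprot_report` list: `tm` and `cwp` (classified
#'   `gelprot_diff` tables), `overlap` (a `gelprot_overlap`),
#'   `class_proportions`, `catalog` (with `conforms` flags), and `counts`
#'   (named integers: `n_pass_tm`, `n_pass_cwp`, `n_shared`,
#'   `n_same_direction`, `n_opposite_direction`).
#' @export
#' @examples
#' rep <- run_fixture_analysis()
#' rep$counts
run_fixture_analysis <- function(fold = 2) {
  classify_fixture <- function(file, case_gel) {
    tab <- read_spot_table(gelprot_example(file))
    pairs <- match_spots(
      filter(tab, .data$gel_id == case_gel),
      filter(tab, .data$gel_id == "CON"),
      by = "spot_id"
    )
    classify_twofold(pairs, fold = fold)
  }
  tm <- classify_fixture("table2_tm_con.csv", "TM")
  cwp <- classify_fixture("table3_cwp_con.csv", "CWP")
  ov <- overlap_analysis(differential_spots(tm), differential_spots(cwp))
  catalog <- check_identification_criteria(read_catalog())
  props <- class_proportions(catalog)
  counts <- c(
    n_pass_tm = sum(tm$passes_twofold),
    n_pass_cwp = sum(cwp$passes_twofold),
    n_shared = ov$n_shared,
    n_same_direction = ov$n_same_direction,
    n_opposite_direction = ov$n_opposite_direction
  )
  structure(
    list(tm = tm, cwp = cwp, overlap = ov, class_proportions = props,
         catalog = catalog, counts = counts, fold = fold),
    class = "gelprot_report"
  )
}

#' @export
print.gelprot_report <- function(x, ...) {
  cat("<differential report> fold threshold:", x$fold, "\n")
  cat("  passing spots: case A =", x$counts[["n_pass_tm"]],
      "| case B =", x$counts[["n_pass_cwp"]], "\n")
  cat("  shared:", x$counts[["n_shared"]],
      "(same direction", x$counts[["n_same_direction"]],
      "/ opposite", x$counts[["n_opposite_direction"]], ")\n")
  invisible(x)
}

#' Run the synthetic end-to-end pipeline
#'
#' Simulates a two-group gel scene with known ground truth, quantifies both
#' gel images (background correction, spot detection, IOD integration),
#' normalizes to ppm, matches spots across gels in coordinate space,
#' classifies under the fold rule, and scores the result against the truth
#' table. Deterministic for a fixed seed.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed for simulation and rendering noise.
#' @param fold Fold threshold (default 2).
#' @param match_tol_px Truth-matching radius in pixels when scoring
#'   detections (default 4).
#' @param detector Optional named list of [detect_spots()] arguments.
#' @return A `gelprot_run` list: `scene`, `spot_tables` (per gel, with
#'   ppm), `diff` (classified pairs), `metrics` (one-row tibble: detection
#'   recall/precision per gel, truth-differential recall, null
#'   false-passing rate, median relative ratio error), `truth_eval`
#'   (per-truth-spot table), `seed`, `fold`.
#' @export
run_pipeline <- function(config = simulation_config(), seed = 1, fold = 2,
                         match_tol_px = 4, detector = list()) {
  scene <- simulate_gel_scene(config, seed = seed)
  quant <- imap(scene$images, function(img, g) {
    do.call(quantify_gel, c(list(img, gel_id = g), detector))
  })
  spot_tables <- map(quant, normalize_ppm)
  pairs <- match_spots(spot_tables$case, spot_tables$control,
                       by = "coordinates")
  diff <- classify_twofold(pairs, fold = fold)
  eval <- evaluate_recovery(diff, quant, scene, match_tol_px = match_tol_px)
  structure(
    list(scene = scene, spot_tables = spot_tables, diff = diff,
         metrics = eval$metrics, truth_eval = eval$truth_eval,
         seed = seed, fold = fold),
    class = "gelprot_run"
  )
}

#' @export
print.gelprot_run <- function(x, ...) {
  m <- x$metrics
  cat("<synthetic run> seed", x$seed, "| fold", x$fold, "\n")
  cat(sprintf("  detection recall %.3f / precision %.3f (case), %.3f / %.3f (control)\n",
              m$detection_recall_case, m$detection_precision_case,
              m$detection_recall_control, m$detection_precision_control))
  cat(sprintf("  differential recall %.3f | null false-pass rate %.3f | median ratio error %.3f\n",
              m$differential_recall, m$null_false_pass_rate,
              m$median_ratio_rel_error))
  invisible(x)
}

# Scores a classified synthetic run against the scene's truth table.
# Truth spots are linked to detections by nearest pixel distance within
# match_tol_px (one detection per truth spot, greedy by distance).
evaluate_recovery <- function(diff, quant, scene, match_tol_px = 4) {
  truth <- scene$truth
  link <- function(detections) {
    if (nrow(detections) == 0) {
      return(tibble(truth_idx = integer(0), spot_id = character(0)))
    }
    d <- sqrt(outer(truth$row_px, detections$row_px, "-")^2 +
                outer(truth$col_px, detections$col_px, "-")^2)
    cand <- which(d <= match_tol_px, arr.ind = TRUE)
    if (nrow(cand) == 0) {
      return(tibble(truth_idx = integer(0), spot_id = character(0)))
    }
    cand <- cand[order(d[cand]), , drop = FALSE]
    used_t <- rep(FALSE, nrow(truth))
    used_d <- rep(FALSE, nrow(detections))
    keep <- matrix(0L, 0, 2)
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (used_t[i] || used_d[j]) next
      used_t[i] <- TRUE; used_d[j] <- TRUE
      keep <- rbind(keep, c(i, j))
    }
    tibble(truth_idx = keep[, 1], spot_id = detections$spot_id[keep[, 2]])
  }
  links <- imap(quant, function(q, g) link(attr(q, "detections")))
  det_stats <- imap(links, function(lk, g) {
    n_det <- nrow(attr(quant[[g]], "detections"))
    tibble(
      gel = g,
      recall = nrow(lk) / nrow(truth),
      precision = if (n_det > 0) nrow(lk) / n_det else NA_real_
    )
  }) %>% list_rbind()
  # Per-truth-spot outcome, keyed through the case-side detection ids
  # (coordinate matching carries the case spot_id for pairs matched on
  # both sides).
  case_link <- links$case
  ctrl_link <- links$control
  truth_eval <- truth %>%
    mutate(truth_idx = row_number()) %>%
    left_join(rename(case_link, case_spot = "spot_id"), by = "truth_idx") %>%
    left_join(rename(ctrl_link, ctrl_spot = "spot_id"), by = "truth_idx")
  diff_case <- diff %>%
    filter(.data$matched != "control_only") %>%
    select(case_spot = "spot_id", case_ratio = "ratio", "direction",
           "passes_twofold", "call")
  diff_ctrl <- diff %>%
    filter(.data$matched == "control_only") %>%
    select(ctrl_spot = "spot_id", ctrl_ratio = "ratio",
           ctrl_passes = "passes_twofold")
  truth_eval <- truth_eval %>%
    left_join(diff_case, by = "case_spot") %>%
    left_join(diff_ctrl, by = "ctrl_spot") %>%
    mutate(
      measured_ratio = dplyr::coalesce(.data$case_ratio, .data$ctrl_ratio),
      passes = dplyr::coalesce(.data$passes_twofold, .data$ctrl_passes,
                               FALSE)
    )
  with_ratio <- filter(truth_eval, is.finite(.data$measured_ratio) &
                         .data$measured_ratio > 0)
  metrics <- tibble(
    detection_recall_case = det_stats$recall[det_stats$gel == "case"],
    detection_precision_case = det_stats$precision[det_stats$gel == "case"],
    detection_recall_control =
      det_stats$recall[det_stats$gel == "control"],
    detection_precision_control =
      det_stats$precision[det_stats$gel == "control"],
    differential_recall =
      mean(truth_eval$passes[truth_eval$differential]),
    null_false_pass_rate =
      mean(truth_eval$passes[!truth_eval$differential]),
    median_ratio_rel_error = median(
      abs(with_ratio$measured_ratio - with_ratio$ratio) / with_ratio$ratio
    )
  )
  list(metrics = metrics, truth_eval = truth_eval, det_stats = det_stats)
}

#' Write the figures of a report
#'
#' Renders the functional-class chart and (for fixture reports) the
#' fold-change chart to PNG files, together with the underlying CSVs, so
#' every figure's numbers are inspectable.
#'
#' @param report A `gelprot_report` from [run_fixture_analysis()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the files written.
#' @export
make_figures <- function(report, dir) {
  if (is.null(report$class_proportions) ||
      nrow(report$class_proportions) == 0) {
    abort("report carries no class counts")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p1 <- plot_class_proportions(report$class_proportions)
  f1 <- file.path(dir, "class_proportions.png")
  ggplot2::ggsave(f1, p1, width = 6, height = 4, dpi = 150)
  c1 <- file.path(dir, "class_proportions.csv")
  readr::write_csv(report$class_proportions, c1)
  files <- c(files, f1, c1)
  if (!is.null(report$tm)) {
    p2 <- ggplot2::autoplot(report$tm) +
      ggplot2::ggtitle("Case A vs control")
    f2 <- file.path(dir, "fold_changes.png")
    ggplot2::ggsave(f2, p2, width = 6, height = 4, dpi = 150)
    c2 <- file.path(dir, "fold_changes.csv")
    readr::write_csv(as_tibble(prepare_report(report$tm)), c2)
    files <- c(files, f2, c2)
  }
  invisible(files)
}
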