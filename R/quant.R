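# Spot quantification on gel images: smooth-background estimation by
# grayscale morphological opening (rolling-ball style), local-maximum spot
# seeding with marker-based region assignment, and integration of the
# background-corrected optical density over each spot mask.

#' Background correction
#'
#' Estimates the smooth background of a gel image as the grayscale
#' morphological opening of a lightly smoothed copy (a rolling-ball-style
#' estimator: the structuring-element radius must be much larger than the
#' spot standard deviation so spots are removed but the background ramp is
#' kept), subtracts it, removes the residual median offset, and floors at
#' zero. Estimator parameters are recorded in the `provenance` attribute.
#'
#' @param image A gel-image matrix (see [render_gel()], [read_gel_image()]).
#' @param radius Structuring-element radius in pixels (default 25).
#' @param presmooth_sigma Gaussian sigma of the pre-smoothing applied to the
#'   background estimate only (default 1.5; 0 disables). Smoothing stops
#'   pixel noise from biasing the morphological opening downwards.
#' @return The corrected image (same class/attributes), floored at 0.
#' @export
correct_background <- function(image, radius = 25, presmooth_sigma = 1.5) {
  size <- 2L * as.integer(radius) + 1L
  if (size > min(dim(image))) {
    abort("structuring element larger than the image")
  }
  px <- unclass(image)
  base <- if (presmooth_sigma > 0) gaussian_smooth(px, presmooth_sigma) else px
  bg <- EBImage::opening(base, EBImage::makeBrush(size, shape = "disc"))
  corrected <- px - bg
  corrected <- corrected - median(corrected)
  corrected <- pmax(corrected, 0)
  out <- gel_image(corrected, bit_depth = attr(image, "bit_depth") %||% 12,
                   calibration = attr(image, "calibration"))
  attr(out, "provenance") <- list(
    method = "grayscale morphological opening",
    radius = radius, presmooth_sigma = presmooth_sigma
  )
  out
}

# Gaussian smoothing via EBImage::filter2 with a normalized Gaussian brush.
gaussian_smooth <- function(px, sigma) {
  size <- 2L * ceiling(3 * sigma) + 1L
  brush <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  as.matrix(EBImage::filter2(px, brush))
}

#' Detect spots on a background-corrected image
#'
#' Seeds spots at local maxima of a Gaussian-smoothed copy of the corrected
#' image (maxima within `min_separation` pixels of a stronger maximum merge
#' into it — the higher peak wins) and assigns each above-threshold pixel
#' to its nearest seed by EBImage's `propagate` (marker-based region
#' assignment), giving disjoint masks. Thresholds are expressed as
#' multiples of a robust noise estimate (median absolute deviation of the
#' smoothed image), so detection is stable under global gel scaling.
#' Detection is deterministic for a fixed image.
#'
#' @param image A background-corrected gel image ([correct_background()]).
#' @param min_separation Minimum seed separation in pixels (default 8).
#' @param threshold_nmad Seed threshold in MADs above the median (default 5).
#' @param mask_nmad Mask (region) threshold in MADs (default 2).
#' @param smooth_sigma Gaussian sigma for the detection image (default 2).
#' @return A tibble of detections (`spot_id`, `row_px`, `col_px`, `pi`,
#'   `mw_kda`, `peak`, `n_px`) with the label matrix (disjoint masks) in
#'   the `labels` attribute.
#' @export
detect_spots <- function(image, min_separation = 8, threshold_nmad = 5,
                         mask_nmad = 2, smooth_sigma = 2) {
  px <- unclass(image)
  sm <- gaussian_smooth(px, smooth_sigma)
  med <- median(sm)
  noise <- mad(sm)
  # Absolute floor at 1e-6 of the dynamic range: a noiseless image has a
  # numerically-zero MAD, and the smoothing convolution leaves float
  # residue (~1e-14 relative) that must not seed spots.
  floor_abs <- 1e-6 * (max(sm) - med)
  thr_seed <- med + max(threshold_nmad * noise, floor_abs)
  thr_mask <- med + max(mask_nmad * noise, floor_abs)
  win <- 2L * as.integer(min_separation) + 1L
  local_max <- sm >= EBImage::dilate(sm, EBImage::makeBrush(win, "disc")) &
    sm > thr_seed
  empty <- tibble(
    spot_id = character(0), row_px = numeric(0), col_px = numeric(0),
    pi = numeric(0), mw_kda = numeric(0), peak = numeric(0),
    n_px = integer(0)
  )
  if (!any(local_max)) {
    attr(empty, "labels") <- matrix(0L, nrow(px), ncol(px))
    return(empty)
  }
  # Plateaus produce several tied maxima: collapse each connected tied
  # component to its centroid, one seed per component.
  comp <- EBImage::bwlabel(local_max)
  idx <- which(comp > 0, arr.ind = TRUE)
  seeds_tbl <- tibble(
    label = comp[comp > 0],
    row = idx[, 1], col = idx[, 2]
  ) %>%
    group_by(.data$label) %>%
    summarise(row = round(mean(.data$row)), col = round(mean(.data$col)),
              .groups = "drop")
  seeds <- matrix(0L, nrow(px), ncol(px))
  seeds[cbind(seeds_tbl$row, seeds_tbl$col)] <- seq_len(nrow(seeds_tbl))
  labels <- EBImage::propagate(sm, seeds, mask = sm > thr_mask)
  labels <- matrix(as.integer(labels), nrow(px), ncol(px))
  # Sub-pixel centroid: intensity-weighted mean of the smoothed image in a
  # small window around each seed, restricted to the seed's own region.
  # (A whole-region centroid would be dragged by residual noise pixels in
  # large masks.)
  ctr_r <- 4L
  region_px <- tabulate(labels[labels > 0], nbins = nrow(seeds_tbl))
  centro <- map(seq_len(nrow(seeds_tbl)), function(k) {
    r0 <- seeds_tbl$row[k]
    c0 <- seeds_tbl$col[k]
    rr <- max(1, r0 - ctr_r):min(nrow(px), r0 + ctr_r)
    cc <- max(1, c0 - ctr_r):min(ncol(px), c0 + ctr_r)
    w <- sm[rr, cc, drop = FALSE] - thr_mask
    w[w < 0] <- 0
    w[labels[rr, cc, drop = FALSE] != k] <- 0
    tot <- sum(w)
    tibble(
      label = k,
      row_px = if (tot > 0) sum(outer(rr, rep(1, length(cc))) * w) / tot
               else as.numeric(r0),
      col_px = if (tot > 0) sum(outer(rep(1, length(rr)), cc) * w) / tot
               else as.numeric(c0),
      n_px = region_px[k],
      peak = sm[r0, c0]
    )
  }) %>% list_rbind()
  cal <- attr(image, "calibration")
  out <- centro %>%
    arrange(.data$label) %>%
    mutate(
      spot_id = sprintf("D%03d", .data$label),
      pi = if (!is.null(cal)) {
        map_col_to_pi(.data$col_px, cal$ph_range, ncol(px))
      } else {
        NA_real_
      },
      mw_kda = if (!is.null(cal)) {
        map_row_to_mw(.data$row_px, cal$mw_range, nrow(px))
      } else {
        NA_real_
      }
    ) %>%
    select("spot_id", "row_px", "col_px", "pi", "mw_kda", "peak", "n_px")
  attr(out, "labels") <- labels
  out
}

#' Integrate optical density over spot masks
#'
#' The IOD of a spot is the sum of the background-corrected intensities
#' over all pixels in its mask. Masks come from [detect_spots()] and are
#' disjoint by construction; this is verified before integrating.
#'
#' @param image The background-corrected gel image the masks were derived
#'   from.
#' @param spots Detections from [detect_spots()] (carrying the label
#'   matrix).
#' @param gel_id Gel identifier stored in the output table.
#' @return A spot-table tibble (`spot_id`, `gel_id`, `pi`, `mw_kda`,
#'   `iod`).
#' @export
integrate_iod <- function(image, spots, gel_id = "gel") {
  labels <- attr(spots, "labels")
  if (is.null(labels)) abort("spots must carry a label matrix (detect_spots)")
  if (!identical(dim(labels), dim(unclass(image)))) {
    abort("label matrix does not match the image dimensions")
  }
  ids <- seq_len(nrow(spots))
  if (nrow(spots) == 0) {
    return(tibble(spot_id = character(0), gel_id = character(0),
                  pi = numeric(0), mw_kda = numeric(0), iod = numeric(0)))
  }
  sums <- tapply(unclass(image)[labels > 0], labels[labels > 0], sum)
  iod <- rep(0, nrow(spots))
  iod[as.integer(names(sums))] <- as.numeric(sums)
  if (any(iod < 0)) abort("negative IOD: image is not background-corrected")
  tibble(
    spot_id = spots$spot_id, gel_id = gel_id,
    pi = spots$pi, mw_kda = spots$mw_kda, iod = iod
  )
}

#' Quantify a gel image end to end
#'
#' Convenience wrapper: background correction, spot detection, and IOD
#' integration with one call.
#'
#' @param image A raw gel image.
#' @param gel_id Gel identifier for the output table.
#' @param radius,presmooth_sigma Passed to [correct_background()].
#' @param ... Passed to [detect_spots()].
#' @return A spot-table tibble with attribute `detections`.
#' @export
quantify_gel <- function(image, gel_id = "gel", radius = 25,
                         presmooth_sigma = 1.5, ...) {
  corrected <- correct_background(image, radius = radius,
                                  presmooth_sigma = presmooth_sigma)
  spots <- detect_spots(corrected, ...)
  out <- integrate_iod(corrected, spots, gel_id = gel_id)
  attr(out, "detections") <- spots
  out
}
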