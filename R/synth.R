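# Synthetic 2-DE gel generator. Produces a ground-truth proteome (spot
# positions in pI x MW space, per-group abundances with a designated
# differential subset), renders each group as a gel image (Gaussian spots,
# global stain scale factor, background, noise, 12-bit clipping), and
# exports everything so downstream stages are testable without real data.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic gel generator. Defaults emulate the
#' study conditions of a pooled-dialysate 2-DE experiment: about 300
#' detectable spots, a 100 kDa membrane-passage cutoff, a linear pH 3-10
#' first dimension, a log-linear molecular-weight second dimension, a
#' two-fold-or-greater abundance shift in a designated subset of spots, a
#' per-gel global stain scale factor, constant background, and Gaussian
#' pixel noise giving a peak signal-to-noise ratio near 10 for the median
#' spot.
#'
#' @param n_spots Number of spots per gel (default 300).
#' @param membrane_cutoff Maximum true molecular weight, kDa (default 100):
#'   solutes above the catheter-membrane cutoff never reach the gel.
#' @param ph_range First-dimension pH range (default `c(3, 10)`, linear).
#' @param mw_range Molecular-weight range in kDa (default `c(10, 100)`);
#'   the lower bound must not exceed `membrane_cutoff`.
#' @param frac_differential Fraction of spots with a true abundance shift
#'   (default 0.15; `round(frac_differential * n_spots)` spots are flagged).
#' @param fold_range Range of the true fold-change magnitude for
#'   differential spots; ratios are drawn log-uniformly from this range and
#'   inverted with probability 1/2 (default `c(2.5, 8)`; the support must
#'   exclude (0.5, 2) so designated spots truly pass a two-fold rule).
#' @param volume_meanlog,volume_sdlog,volume_min Log-normal baseline spot
#'   volume parameters and a lower truncation bound (arbitrary intensity
#'   units).
#' @param gel_scale_factors Named per-gel multiplicative stain factors
#'   (default `c(case = 1, control = 1.3)`), emulating gel-to-gel staining
#'   differences that ppm normalization must remove.
#' @param background_level Constant background intensity (default 40).
#' @param noise_sd Gaussian pixel noise standard deviation (default 5; 0
#'   disables).
#' @param poisson Add Poisson (shot) noise on top (default `FALSE`).
#' @param spot_sd Spot Gaussian standard deviations in pixels,
#'   `(pI axis, MW axis)` (default `c(2.5, 2.5)`).
#' @param image_dim Image size in pixels, `(rows, cols)` (default
#'   `c(1000, 1000)`).
#' @param min_separation_px Minimum distance between spot centers in pixels
#'   (default 12), so the benchmark scene respects the detector's
#'   minimum-separation assumption.
#' @param edge_margin_px Margin kept free of spot centers (default 15 px),
#'   so rendered volumes are conserved within the frame.
#' @param bit_depth Image bit depth (default 12); values clip at
#'   `2^bit_depth - 1` and the clipped fraction is reported.
#' @return A `gelprot_sim_config` list.
#' @export
simulation_config <- function(n_spots = 300,
                              membrane_cutoff = 100,
                              ph_range = c(3, 10),
                              mw_range = c(10, 100),
                              frac_differential = 0.15,
                              fold_range = c(2.5, 8),
                              volume_meanlog = log(2000),
                              volume_sdlog = 1.2,
                              volume_min = 300,
                              gel_scale_factors = c(case = 1, control = 1.3),
                              background_level = 40,
                              noise_sd = 5,
                              poisson = FALSE,
                              spot_sd = c(2.5, 2.5),
                              image_dim = c(1000, 1000),
                              min_separation_px = 12,
                              edge_margin_px = 15,
                              bit_depth = 12) {
  if (frac_differential < 0 || frac_differential > 1) {
    abort("frac_differential must lie in [0, 1]")
  }
  if (ph_range[1] >= ph_range[2]) abort("ph_range must be increasing")
  if (mw_range[1] > membrane_cutoff) {
    abort("mw_range lower bound exceeds the membrane cutoff")
  }
  if (any(gel_scale_factors <= 0)) abort("gel scale factors must be > 0")
  if (any(fold_range < 2) || fold_range[1] > fold_range[2]) {
    abort("fold_range must be increasing with both ends >= 2")
  }
  structure(
    list(
      n_spots = n_spots, membrane_cutoff = membrane_cutoff,
      ph_range = ph_range, mw_range = mw_range,
      frac_differential = frac_differential, fold_range = fold_range,
      volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog,
      volume_min = volume_min, gel_scale_factors = gel_scale_factors,
      background_level = background_level, noise_sd = noise_sd,
      poisson = poisson, spot_sd = spot_sd, image_dim = image_dim,
      min_separation_px = min_separation_px,
      edge_margin_px = edge_margin_px, bit_depth = bit_depth
    ),
    class = "gelprot_sim_config"
  )
}

#' @export
print.gelprot_sim_config <- function(x, ...) {
  cat("<simulation config>\n")
  cat("  spots:", x$n_spots, "| differential fraction:",
      x$frac_differential, "| fold range:", x$fold_range[1], "-",
      x$fold_range[2], "\n")
  cat("  pH", x$ph_range[1], "-", x$ph_range[2], "| MW", x$mw_range[1], "-",
      min(x$mw_range[2], x$membrane_cutoff), "kDa (cutoff",
      x$membrane_cutoff, "kDa)\n")
  cat("  image:", x$image_dim[1], "x", x$image_dim[2], "px,", x$bit_depth,
      "bit | background", x$background_level, "| noise sd", x$noise_sd, "\n")
  invisible(x)
}

# --- axis calibration -------------------------------------------------------

#' Axis calibration between (pI, MW) and pixel coordinates
#'
#' The first dimension maps pI linearly onto columns over the pH range; the
#' second maps log10(MW) linearly onto rows, with the highest molecular
#' weight at row 0 (top of the gel), emulating a linear immobilized pH
#' gradient and an approximately log-linear gradient-gel migration.
#'
#' @param pi,col pI values / fractional column positions.
#' @param mw,row Molecular weights (kDa) / fractional row positions.
#' @param ph_range,mw_range Axis ranges.
#' @param n_col,n_row Image dimensions in pixels.
#' @return Numeric vector of positions (fractional pixels) or axis values.
#' @export
#' @examples
#' map_pi_to_col(6.5, c(3, 10), 1000)  # 500
map_pi_to_col <- function(pi, ph_range, n_col) {
  (pi - ph_range[1]) / diff(ph_range) * n_col
}

#' @rdname map_pi_to_col
#' @export
map_col_to_pi <- function(col, ph_range, n_col) {
  ph_range[1] + col / n_col * diff(ph_range)
}

#' @rdname map_pi_to_col
#' @export
map_mw_to_row <- function(mw, mw_range, n_row) {
  lr <- log10(rev(mw_range))
  (log10(mw) - lr[1]) / (lr[2] - lr[1]) * n_row
}

#' @rdname map_pi_to_col
#' @export
map_row_to_mw <- function(row, mw_range, n_row) {
  lr <- log10(rev(mw_range))
  10^(lr[1] + row / n_row * (lr[2] - lr[1]))
}

# --- truth simulation -------------------------------------------------------

#' Simulate a ground-truth proteome
#'
#' Draws `n_spots` spot centers (uniform over the usable gel area with a
#' minimum center separation, truncated at the membrane cutoff), log-normal
#' baseline volumes, and designates exactly
#' `round(frac_differential * n_spots)` spots as differential with true
#' case/control ratios drawn log-uniformly from `fold_range` (inverted with
#' probability 1/2). Case and control volumes split the fold symmetrically
#' (`case = base * sqrt(r)`, `control = base / sqrt(r)`), keeping the
#' group-mean abundance at the baseline; non-differential spots have ratio
#' exactly 1.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; the truth table is deterministic given
#'   `config` and `seed`.
#' @return A tibble (`spot_id`, `row_px`, `col_px`, `pi`, `mw_kda`,
#'   `base_volume`, `differential`, `ratio`, `volume_case`,
#'   `volume_control`).
#' @export
simulate_proteome <- function(config = simulation_config(), seed = 1) {
  stopifnot(inherits(config, "gelprot_sim_config"))
  set.seed(seed)
  n <- config$n_spots
  dim <- config$image_dim
  margin <- config$edge_margin_px
  minsep2 <- config$min_separation_px^2
  rows <- numeric(n)
  cols <- numeric(n)
  placed <- 0L
  attempts <- 0L
  max_attempts <- 2000L * max(n, 1L)
  while (placed < n) {
    if (attempts > max_attempts) {
      abort("could not place spots with the requested minimum separation")
    }
    attempts <- attempts + 1L
    r <- runif(1, margin, dim[1] - margin)
    c <- runif(1, margin, dim[2] - margin)
    if (placed > 0L) {
      d2 <- (rows[seq_len(placed)] - r)^2 + (cols[seq_len(placed)] - c)^2
      if (min(d2) < minsep2) next
    }
    placed <- placed + 1L
    rows[placed] <- r
    cols[placed] <- c
  }
  mw <- map_row_to_mw(rows, c(config$mw_range[1],
                              min(config$mw_range[2],
                                  config$membrane_cutoff)), dim[1])
  pi <- map_col_to_pi(cols, config$ph_range, dim[2])
  base <- pmax(rlnorm(n, config$volume_meanlog, config$volume_sdlog),
               config$volume_min)
  n_diff <- round(config$frac_differential * n)
  differential <- rep(FALSE, n)
  if (n_diff > 0) differential[sample.int(n, n_diff)] <- TRUE
  ratio <- rep(1, n)
  if (n_diff > 0) {
    mag <- exp(runif(n_diff, log(config$fold_range[1]),
                     log(config$fold_range[2])))
    flip <- runif(n_diff) < 0.5
    ratio[differential] <- ifelse(flip, 1 / mag, mag)
  }
  tibble(
    spot_id = sprintf("S%03d", seq_len(n)),
    row_px = rows, col_px = cols, pi = pi, mw_kda = mw,
    base_volume = base, differential = differential, ratio = ratio,
    volume_case = base * sqrt(ratio),
    volume_control = base / sqrt(ratio)
  )
}

# --- rendering --------------------------------------------------------------

#' Render a gel image from a truth table
#'
#' Each spot becomes a 2-D Gaussian whose integrated volume equals its true
#' group volume times the gel scale factor; constant background and
#' Gaussian (optionally Poisson) noise are added, and values are clipped to
#' the bit-depth range. The clipped pixel fraction and the number of spots
#' dropped for falling outside the frame are reported as attributes.
#'
#' @param truth A truth table from [simulate_proteome()].
#' @param group `"case"` or `"control"`: which volume column to render.
#' @param config The [simulation_config()] used to build `truth`.
#' @param scale Global stain scale factor for this gel (defaults to the
#'   configured factor for the group).
#' @param seed Integer seed for the noise draw.
#' @return A gel-image matrix with `bit_depth`, `calibration`, `scale`,
#'   `clipped_fraction` and `n_dropped` attributes.
#' @export
render_gel <- function(truth, group = c("case", "control"),
                       config = simulation_config(), scale = NULL,
                       seed = 1) {
  group <- arg_match(group)
  stopifnot(inherits(config, "gelprot_sim_config"))
  scale <- scale %||%
    unname(config$gel_scale_factors[[group]] %||% 1)
  dim <- config$image_dim
  img <- matrix(0, dim[1], dim[2])
  sd_c <- config$spot_sd[1]
  sd_r <- config$spot_sd[2]
  half <- ceiling(5 * max(sd_r, sd_c))
  vol <- truth[[paste0("volume_", group)]] * scale
  n_dropped <- 0L
  for (i in seq_len(nrow(truth))) {
    r0 <- truth$row_px[i]
    c0 <- truth$col_px[i]
    if (r0 < 1 || r0 > dim[1] || c0 < 1 || c0 > dim[2]) {
      n_dropped <- n_dropped + 1L
      next
    }
    rr <- max(1, floor(r0 - half)):min(dim[1], ceiling(r0 + half))
    cc <- max(1, floor(c0 - half)):min(dim[2], ceiling(c0 + half))
    gr <- exp(-(rr - r0)^2 / (2 * sd_r^2))
    gc <- exp(-(cc - c0)^2 / (2 * sd_c^2))
    amp <- vol[i] / (2 * pi * sd_r * sd_c)
    img[rr, cc] <- img[rr, cc] + amp * outer(gr, gc)
  }
  if (n_dropped > 0) {
    warn(paste0(n_dropped, " spot(s) fell outside the image and were dropped"))
  }
  img <- img + config$background_level
  set.seed(seed)
  if (config$poisson) img <- matrix(rpois(length(img), img), dim[1], dim[2])
  if (config$noise_sd > 0) {
    img <- img + matrix(rnorm(length(img), 0, config$noise_sd),
                        dim[1], dim[2])
  }
  maxval <- 2^config$bit_depth - 1
  clipped <- mean(img > maxval | img < 0)
  img <- pmin(pmax(img, 0), maxval)
  out <- gel_image(
    img, bit_depth = config$bit_depth,
    calibration = list(
      ph_range = config$ph_range,
      mw_range = c(config$mw_range[1],
                   min(config$mw_range[2], config$membrane_cutoff))
    )
  )
  attr(out, "scale") <- scale
  attr(out, "clipped_fraction") <- clipped
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Simulate a complete two-group gel scene
#'
#' Convenience wrapper: simulates the truth table and renders one gel per
#' configured scale factor (one `case`, one `control`).
#'
#' @inheritParams simulate_proteome
#' @return A `gelprot_scene` list with elements `config`, `truth`,
#'   `images` (named list), `scale_factors`, `seed`.
#' @export
simulate_gel_scene <- function(config = simulation_config(), seed = 1) {
  truth <- simulate_proteome(config, seed = seed)
  groups <- intersect(names(config$gel_scale_factors), c("case", "control"))
  images <- setNames(
    map(seq_along(groups), function(i) {
      render_gel(truth, groups[[i]], config,
                 scale = config$gel_scale_factors[[groups[[i]]]],
                 seed = seed + i)
    }),
    groups
  )
  structure(
    list(config = config, truth = truth, images = images,
         scale_factors = config$gel_scale_factors, seed = seed),
    class = "gelprot_scene"
  )
}

#' @export
print.gelprot_scene <- function(x, ...) {
  cat("<gel scene> ", nrow(x$truth), " spots, ",
      sum(x$truth$differential), " differential, ",
      length(x$images), " gel image(s)\n", sep = "")
  invisible(x)
}

#' Export a simulated scene to disk
#'
#' Writes the truth table as CSV, each gel image as 16-bit TIFF (with its
#' calibration sidecar), and the configuration as JSON, so every
#' downstream stage can be exercised from files alone.
#'
#' @param scene A scene from [simulate_gel_scene()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
export_truth <- function(scene, dir) {
  stopifnot(inherits(scene, "gelprot_scene"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  truth_path <- file.path(dir, "truth.csv")
  readr::write_csv(scene$truth, truth_path, na = "")
  files <- c(files, truth_path)
  for (g in names(scene$images)) {
    p <- file.path(dir, paste0("gel_", g, ".tif"))
    write_gel_image(scene$images[[g]], p)
    files <- c(files, p, paste0(p, ".json"))
  }
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(unclass(scene$config), cfg_path, auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, cfg_path)
  invisible(files)
}
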