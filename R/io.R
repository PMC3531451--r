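# Readers and writers for the external formats the pipeline touches:
# headered CSV spot tables, FASTA sequence collections, plain/MGF peak
# lists, 16-bit TIFF gel images (carrying 12-bit data), and JSON reports.

#' Read a spot table
#'
#' Reads a delimited spot-quantification table into a tibble. The file must
#' carry `spot_id` and `gel_id` columns and at least one of `iod` (raw,
#' background-corrected integrated optical density) or `ppm` (normalized
#' parts-per-million of total gel intensity). Optional columns `protein`,
#' `pi` and `mw_kda` are kept when present. Row order is preserved; unset
#' numeric fields are empty cells, never 0 (an IOD of 0 means an absent
#' spot, not a missing measurement).
#'
#' @param path File path.
#' @param delim Field delimiter (default comma).
#' @return A spot-table tibble with one row per spot per gel.
#' @export
#' @examples
#' tm_con <- read_spot_table(gelprot_example("table2_tm_con.csv"))
#' dplyr::count(tm_con, gel_id)
read_spot_table <- function(path, delim = ",") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  tab <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = "c"),
    trim_ws = TRUE, progress = FALSE, show_col_types = FALSE
  )
  prob <- readr::problems(tab)
  if (nrow(prob) > 0) {
    abort(paste0("malformed spot table '", path, "': parse failure at line ",
                 prob$row[[1]] + 1L, " (", prob$expected[[1]], ")"))
  }
  need <- c("spot_id", "gel_id")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0) {
    abort(paste0("spot table lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!any(c("iod", "ppm") %in% names(tab))) {
    abort("spot table must have at least one of 'iod' or 'ppm'")
  }
  for (col in intersect(c("pi", "mw_kda", "iod", "ppm"), names(tab))) {
    raw <- tab[[col]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
    if (length(bad) > 0) {
      abort(paste0("malformed spot table '", path, "': non-numeric '",
                   raw[bad[[1]]], "' in column '", col, "' at line ",
                   bad[[1]] + 1L))
    }
    tab[[col]] <- val
  }
  validate_spot_table(tab)
  tab
}

#' Validate a spot table
#'
#' Checks the spot-table invariants: required columns present, `iod`/`ppm`
#' non-negative, `ppm` at most 1e6, and `spot_id` unique within each gel.
#' With `complete = TRUE` additionally requires the ppm values of every gel
#' to sum to 1e6 (within 1e-6 relative tolerance) — appropriate for whole-gel
#' tables but not for differential subsets.
#'
#' @param x A spot-table data frame.
#' @param complete Enforce the per-gel ppm-sum invariant.
#' @return `x`, invisibly.
#' @export
validate_spot_table <- function(x, complete = FALSE) {
  stopifnot(is.data.frame(x))
  miss <- setdiff(c("spot_id", "gel_id"), names(x))
  if (length(miss) > 0) {
    abort(paste0("spot table lacks required column(s): ",
                 paste(miss, collapse = ", ")))
  }
  dup <- x %>%
    filter(!is.na(.data$spot_id)) %>%
    count(.data$gel_id, .data$spot_id) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("duplicate spot_id within gel: ",
                 paste0(dup$gel_id, "/", dup$spot_id, collapse = ", ")))
  }
  if ("iod" %in% names(x) && any(x$iod < 0, na.rm = TRUE)) {
    abort("iod must be >= 0")
  }
  if ("ppm" %in% names(x)) {
    if (any(x$ppm < 0 | x$ppm > 1e6, na.rm = TRUE)) {
      abort("ppm must lie in [0, 1e6]")
    }
    if (complete) {
      sums <- x %>%
        group_by(.data$gel_id) %>%
        summarise(s = sum(.data$ppm), .groups = "drop")
      off <- abs(sums$s - 1e6) / 1e6 > 1e-6
      if (any(off)) {
        abort(paste0("ppm does not sum to 1e6 for gel(s): ",
                     paste(sums$gel_id[off], collapse = ", ")))
      }
    }
  }
  invisible(x)
}

#' Write a spot table
#'
#' Comma-delimited UTF-8 with the documented column names; missing numeric
#' values are written as empty cells so that an absent measurement is never
#' confused with a zero IOD. `write_spot_table()` then `read_spot_table()`
#' round-trips field-for-field at full stored precision.
#'
#' @param x A spot-table data frame.
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_spot_table <- function(x, path) {
  validate_spot_table(x)
  readr::write_csv(x, path, na = "")
  invisible(x)
}

#' Read protein sequences from FASTA
#'
#' Parses a FASTA file into one row per record. The accession is taken from
#' UniProt-style headers (`sp|P02144|MYG_HUMAN` gives `P02144`) or, for bare
#' headers, the first whitespace-delimited token. Sequences are uppercased,
#' whitespace-stripped, and validated against the 20 standard one-letter
#' codes.
#'
#' @param path FASTA file path.
#' @return A tibble with `accession`, `name`, `sequence`, `length`.
#' @export
#' @examples
#' read_fasta(gelprot_example("P02144.fasta"))
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- toupper(gsub("[[:space:]]", "", as.character(set)))
  if (length(seqs) > 0) check_residues(seqs, "FASTA sequence")
  first_tok <- sub("[[:space:]].*$", "", headers)
  accession <- ifelse(
    grepl("^[a-z]{2}\\|[^|]+\\|", first_tok),
    sub("^[a-z]{2}\\|([^|]+)\\|.*$", "\\1", first_tok),
    first_tok
  )
  tibble(
    accession = accession,
    name = headers,
    sequence = unname(seqs),
    length = unname(nchar(seqs))
  )
}

#' Write protein sequences to FASTA
#'
#' @param x A data frame with `accession` and `sequence` columns (a `name`
#'   column, when present, is used as the header).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(all(c("accession", "sequence") %in% names(x)))
  headers <- if ("name" %in% names(x)) x$name else x$accession
  set <- Biostrings::BStringSet(x$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 60)
  invisible(x)
}

#' Read a peak list
#'
#' Reads centroided peptide m/z values from either a plain text file (one
#' mass per line, `#` comments allowed) or an MGF file (masses taken from
#' the first column of the ion lines inside `BEGIN IONS`/`END IONS`
#' blocks). Values are sorted ascending; duplicates are retained.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"plain"`, or `"mgf"`.
#' @return A tibble with columns `source_id` and `mz` (Da), sorted by `mz`.
#' @export
read_peaklist <- function(path, format = c("auto", "plain", "mgf")) {
  format <- arg_match(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.mgf$", path, ignore.case = TRUE)) "mgf" else "plain"
  }
  lines <- readr::read_lines(path, progress = FALSE)
  source_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "plain") {
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    mz <- suppressWarnings(as.numeric(sub("[\t ,;].*$", "", lines)))
    if (anyNA(mz)) {
      bad <- which(is.na(mz))[[1]]
      abort(paste0("non-numeric peak-list line: '", lines[[bad]], "'"))
    }
  } else {
    inside <- FALSE
    mz <- numeric(0)
    for (ln in trimws(lines)) {
      if (!nzchar(ln)) next
      if (toupper(ln) == "BEGIN IONS") {
        inside <- TRUE
      } else if (toupper(ln) == "END IONS") {
        inside <- FALSE
      } else if (inside && !grepl("=", ln, fixed = TRUE)) {
        v <- suppressWarnings(as.numeric(strsplit(ln, "[\t ]+")[[1]][[1]]))
        if (is.na(v)) abort(paste0("non-numeric MGF ion line: '", ln, "'"))
        mz <- c(mz, v)
      }
    }
  }
  if (any(mz <= 0)) abort("peak list contains non-positive masses")
  tibble(source_id = source_id, mz = sort(mz))
}

#' Write an analysis report as JSON
#'
#' Serializes differential and identification summaries to a machine-readable
#' JSON document with a stable key order; [read_report()] restores it. The
#' top-level `counts` element carries the headline integers (spots passing
#' the fold rule per comparison, overlap size and direction split).
#'
#' @param results A report list, e.g. from [run_fixture_analysis()] or any
#'   list of data frames / scalars.
#' @param path Output path.
#' @return `results`, invisibly.
#' @export
write_report <- function(results, path) {
  ok <- tryCatch({
    jsonlite::write_json(
      prepare_report(results), path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
    )
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste0("cannot write report to '", path, "': ",
                 conditionMessage(ok)))
  }
  invisible(results)
}

# Strips non-serializable attributes/classes so the JSON round-trips;
# named atomic vectors become objects so their names survive.
prepare_report <- function(x) {
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  if (is.data.frame(x)) {
    return(as.data.frame(lapply(x, function(col) {
      if (is.list(col)) NULL else col
    })))
  }
  if (is.list(x)) return(lapply(x, prepare_report))
  x
}

#' Read a JSON report
#'
#' @param path Path to a JSON document written by [write_report()].
#' @return A list; tabular elements become tibbles.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  out <- jsonlite::read_json(path, simplifyVector = TRUE)
  rapply(out, as_tibble, classes = "data.frame", how = "replace")
}

#' Read and write gel images
#'
#' Gel images are non-negative intensity grids with 12-bit semantics
#' (values in \[0, 4095\]) stored in a 16-bit grayscale TIFF container,
#' with the axis calibration (pH range, molecular-weight range) carried in
#' attributes and restored from a JSON sidecar written next to the image.
#'
#' @param path TIFF path. `write_gel_image()` writes `<path>` and
#'   `<path>.json` (the calibration sidecar).
#' @param image A gel-image matrix as produced by [render_gel()], with
#'   `bit_depth` and `calibration` attributes.
#' @return `read_gel_image()` returns the image matrix with attributes
#'   restored; `write_gel_image()` returns the image invisibly.
#' @export
write_gel_image <- function(image, path) {
  bit_depth <- attr(image, "bit_depth") %||% 12
  maxval <- 2^bit_depth - 1
  if (any(image < 0 | image > maxval)) {
    abort("pixel values outside the stated bit depth")
  }
  tiff::writeTIFF(round(unclass(image)) / (2^16 - 1), path,
                  bits.per.sample = 16L, compression = "none")
  meta <- list(
    bit_depth = bit_depth,
    calibration = attr(image, "calibration")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(image)
}

#' @rdname write_gel_image
#' @export
read_gel_image <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  pix <- round(tiff::readTIFF(path) * (2^16 - 1))
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list(bit_depth = 12, calibration = NULL)
  }
  gel_image(pix, bit_depth = meta$bit_depth,
            calibration = meta$calibration)
}

# Constructor for the gel-image matrix type.
gel_image <- function(pixels, bit_depth = 12, calibration = NULL) {
  pixels <- as.matrix(pixels)
  structure(
    pixels,
    bit_depth = bit_depth,
    calibration = calibration,
    class = c("gelprot_image", class(pixels))
  )
}

#' @export
print.gelprot_image <- function(x, ...) {
  cal <- attr(x, "calibration")
  cat("<gel image> ", nrow(x), " x ", ncol(x), " px, ",
      attr(x, "bit_depth"), "-bit\n", sep = "")
  if (!is.null(cal)) {
    cat("  pI axis: pH", cal$ph_range[1], "-", cal$ph_range[2],
        " | MW axis:", cal$mw_range[1], "-", cal$mw_range[2], "kDa\n")
  }
  invisible(x)
}
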