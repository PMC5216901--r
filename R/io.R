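#' Write / read a streak image as CSV
#'
#' The on-disk layout is a wide matrix: metadata as leading `# key: value`
#' comment lines, then a header row whose first cell is `time` and remaining
#' cells are the wavelength grid (nm), then one row per time point (ps) with
#' the intensities. Full float precision is preserved, so a write/read
#' round-trip is lossless.
#'
#' @param image A `streak_image` tibble.
#' @param path File path.
#' @return `path`, invisibly (writer); a `streak_image` (reader).
#' @export
write_streak_csv <- function(image, path) {
  p <- unpack_image(image)
  meta <- c(sprintf("# irf_center: %.17g", p$mu),
            sprintf("# irf_sigma: %.17g", p$sigma),
            sprintf("# time_range: %s", attr(image, "time_range") %||% "TR1"))
  header <- paste(c("time", sprintf("%.17g", p$wavelength)), collapse = ",")
  body <- vapply(seq_along(p$time), function(i) {
    paste(sprintf("%.17g", c(p$time[i], p$y[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(meta, header, body), path)
  invisible(path)
}

#' @rdname write_streak_csv
#' @export
read_streak_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- parse_meta(lines[meta_lines])
  body <- if (length(meta_lines)) lines[-meta_lines] else lines
  if (length(body) < 2L) abort("Malformed streak CSV: missing header or data rows.")
  header <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "time") {
    abort("Malformed streak CSV header: first column must be `time`.")
  }
  wl <- as.numeric(header[-1])
  if (anyNA(wl)) abort("Malformed streak CSV header: non-numeric wavelengths.")
  n_col <- length(header)
  rows <- lapply(seq_along(body[-1]), function(i) {
    cells <- as.numeric(strsplit(body[i + 1L], ",", fixed = TRUE)[[1]])
    if (length(cells) != n_col || anyNA(cells)) {
      abort(sprintf("Malformed streak CSV at data row %d.", i))
    }
    cells
  })
  m <- do.call(rbind, rows)
  t_grid <- m[, 1]
  if (is.unsorted(t_grid, strictly = TRUE)) {
    abort("Streak CSV time axis is not strictly increasing.")
  }
  if (is.unsorted(wl, strictly = TRUE)) {
    abort("Streak CSV wavelength axis is not strictly increasing.")
  }
  df <- tibble::tibble(
    time = rep(t_grid, times = length(wl)),
    wavelength = rep(wl, each = length(t_grid)),
    intensity = as.vector(m[, -1, drop = FALSE])
  )
  new_streak_image(df,
                   irf_center = as.numeric(meta[["irf_center"]] %||% 0),
                   irf_sigma = as.numeric(meta[["irf_sigma"]] %||% 0),
                   time_range = meta[["time_range"]] %||% "TR1")
}

parse_meta <- function(lines) {
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}

#' Write / read a spectrum as two-column TSV
#'
#' Columns `wavelength` and `value`, preceded by `# key: value` metadata
#' lines recording the spectrum kind and temperature.
#'
#' @param spec A [spectrum_record()].
#' @param path File path.
#' @return `path`, invisibly (writer); a `spectrum_record` (reader).
#' @export
write_spectrum_tsv <- function(spec, path) {
  meta <- c(sprintf("# kind: %s", attr(spec, "kind") %||% "absorption"),
            sprintf("# temperature: %s", attr(spec, "temperature") %||% 293))
  body <- sprintf("%.17g\t%.17g", spec$wavelength, spec$value)
  writeLines(c(meta, "wavelength\tvalue", body), path)
  invisible(path)
}

#' @rdname write_spectrum_tsv
#' @export
read_spectrum_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path)
  meta_lines <- grep("^#", lines)
  meta <- parse_meta(lines[meta_lines])
  df <- readr::read_tsv(I(if (length(meta_lines)) lines[-meta_lines] else lines),
                        show_col_types = FALSE)
  spectrum_record(df$wavelength, df$value,
                  kind = meta[["kind"]] %||% "absorption",
                  temperature = as.numeric(meta[["temperature"]] %||% 293))
}

#' Write / read a protein-by-fraction intensity table as TSV
#'
#' Long format with columns `protein`, `fraction`, `intensity` (plus any
#' extra identity columns, which are preserved).
#'
#' @param table Long fraction-intensity tibble.
#' @param path File path.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_fraction_tsv <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(path)
}

#' @rdname write_fraction_tsv
#' @export
read_fraction_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  check_fraction_table(tbl)
  if (!is.factor(tbl$fraction)) {
    tbl$fraction <- factor(tbl$fraction, levels = unique(tbl$fraction))
  }
  tbl
}

#' Write / read a pigment peak-area table as TSV
#'
#' Columns `pigment`, `area`, `response_factor`.
#'
#' @param areas Pigment area tibble (see [gen_pigment_areas()]).
#' @param path File path.
#' @return `path`, invisibly (writer); a tibble (reader).
#' @export
write_pigment_tsv <- function(areas, path) {
  readr::write_tsv(areas, path)
  invisible(path)
}

#' @rdname write_pigment_tsv
#' @export
read_pigment_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  readr::read_tsv(path, show_col_types = FALSE)
}
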