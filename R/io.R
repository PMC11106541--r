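# Instrument-export ingestion. One CSV dialect is fixed package-wide:
# comma separator, header required, decimal point, temperatures in
# degrees C. Long format: one row per (well, temperature) reading.

read_table_checked <- function(path, required, delim = ",") {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  raw <- suppressWarnings(readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = "c"),
    progress = FALSE))
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop_input("%s: missing required column(s): %s", path,
               paste(missing, collapse = ", "))
  }
  raw
}

as_numeric_checked <- function(x, col, path) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad) > 0) {
    # +1 for the header line
    stop_input("%s: non-numeric value in column '%s' at line(s) %s", path,
               col, paste(head(bad + 1L, 5), collapse = ", "))
  }
  out
}

#' Read melt curves from a long-format CSV export
#'
#' Required columns: `well`, `temperature_C`, `fluorescence`. Optional
#' columns `protein`, `compound`, `conc_mM` annotate each well, or a
#' sidecar plate map can supply them. Rows are sorted by temperature
#' within each well; malformed cells are rejected with their line number.
#'
#' @param path CSV file path.
#' @param plate_map Optional tibble with `well` plus any of `protein`,
#'   `compound`, `conc_mM` to annotate wells.
#' @param delim Field delimiter (`","`; pass `"\t"` for TSV exports).
#'
#' @return A named list of [melt_curve()] objects, keyed by well.
#' @export
read_melt_csv <- function(path, plate_map = NULL, delim = ",") {
  raw <- read_table_checked(path, c("well", "temperature_C", "fluorescence"),
                            delim = delim)
  raw$temperature_C <- as_numeric_checked(raw$temperature_C,
                                          "temperature_C", path)
  raw$fluorescence <- as_numeric_checked(raw$fluorescence,
                                         "fluorescence", path)
  if ("conc_mM" %in% names(raw)) {
    raw$conc_mM <- as_numeric_checked(raw$conc_mM, "conc_mM", path)
  }
  if (anyNA(raw$temperature_C) || anyNA(raw$fluorescence)) {
    stop_input("%s: missing temperature or fluorescence values", path)
  }
  if (!is.null(plate_map)) {
    plate_map <- tibble::as_tibble(plate_map)
    raw <- dplyr::left_join(
      raw[, setdiff(names(raw), setdiff(names(plate_map), "well"))],
      plate_map, by = "well")
  }
  wells <- split(raw, raw$well)
  out <- lapply(wells, function(w) {
    w <- w[order(w$temperature_C), ]
    melt_curve(
      w$temperature_C, w$fluorescence, well = w$well[1],
      protein = if ("protein" %in% names(w)) w$protein[1] else NA_character_,
      compound = if ("compound" %in% names(w)) w$compound[1] else NA_character_,
      conc_mM = if ("conc_mM" %in% names(w)) w$conc_mM[1] else NA_real_)
  })
  out[order(names(out))]
}

#' Write melt curves to a long-format CSV
#'
#' Inverse of [read_melt_csv()]: one row per reading, stable column order,
#' UTF-8, LF line endings.
#'
#' @param curves A list of [melt_curve()] objects.
#' @param path Output file path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_melt_csv <- function(curves, path, delim = ",") {
  if (inherits(curves, "melt_curve")) curves <- list(curves)
  tab <- dplyr::bind_rows(lapply(curves, as_tibble))
  readr::write_delim(tab, path, delim = delim, eol = "\n")
  invisible(path)
}

#' Read or write a per-well Tm-call table
#'
#' TSV with columns `well`, `protein`, `compound`, `conc_mM`, `tm_c`,
#' `depth`, `flags`.
#'
#' @param calls Tibble of per-well calls.
#' @param path File path.
#' @return `read_tm_tsv()` returns a tibble; `write_tm_tsv()` returns
#'   `path` invisibly.
#' @export
write_tm_tsv <- function(calls, path) {
  readr::write_tsv(tibble::as_tibble(calls), path, eol = "\n")
  invisible(path)
}

#' @rdname write_tm_tsv
#' @export
read_tm_tsv <- function(path) {
  raw <- read_table_checked(path, c("well", "tm_c"), delim = "\t")
  for (col in intersect(c("tm_c", "depth", "conc_mM", "shift", "wt_gap",
                          "rmsd", "dyn_range", "alone_range"), names(raw))) {
    raw[[col]] <- as_numeric_checked(raw[[col]], col, path)
  }
  for (col in intersect(c("hit", "interference"), names(raw))) {
    raw[[col]] <- as.logical(raw[[col]])
  }
  raw
}
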