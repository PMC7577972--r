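# Plain-text CSV interchange: one file per station per kind, a '#'-comment
# header declaring the kind and the units of every column, comma separator,
# '.' decimal, empty fields for missing values.

.profile_specs <- list(
  shear = list(
    required = c("time_s", "shear_1_per_s", "depth_m", "temperature_C"),
    monotone = "depth_m"
  ),
  ctd = list(
    required = c("depth_m", "theta_C", "sigma_theta_kg_m3", "fluorescence"),
    monotone = "depth_m"
  ),
  bottle = list(
    required = c(
      "station", "depth_m", "nitrate_mmol_m3", "phosphate_mmol_m3",
      "chl_mg_m3"
    ),
    monotone = NULL
  ),
  profile = list(required = c("depth_m"), monotone = NULL)
)

#' Write a profile table with kind and unit metadata
#'
#' Writes a data.frame as CSV preceded by comment lines declaring the kind
#' and per-column units, plus any extra metadata (e.g. `fall_speed`).
#'
#' @param df data.frame to write; column names should carry units as
#'   `_<unit>` suffixes.
#' @param path output file path.
#' @param kind one of `"shear"`, `"ctd"`, `"bottle"`, `"profile"`.
#' @param meta named character/numeric vector of extra header metadata.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(df, path, kind, meta = NULL) {
  kind <- match.arg(kind, names(.profile_specs))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind: %s", kind), con)
  writeLines(sprintf("# columns: %s", paste(names(df), collapse = ",")), con)
  if (!is.null(meta)) {
    for (nm in names(meta)) {
      writeLines(sprintf("# %s: %s", nm, format(meta[[nm]], digits = 17)), con)
    }
  }
  utils::write.table(df, con,
    sep = ",", row.names = FALSE, col.names = TRUE,
    quote = FALSE, na = ""
  )
  invisible(path)
}

#' Read a profile table, validating kind and columns
#'
#' Parses the comment header, checks the declared kind against `kind` (if
#' given), verifies required columns and depth monotonicity, and reports
#' malformed rows with line numbers.
#'
#' @param path CSV file written by [write_profile_csv()] (or compatible).
#' @param kind expected kind; `NULL` accepts whatever the file declares.
#' @return data.frame with attributes `kind` and `meta` (named list of
#'   header metadata).
#' @export
read_profiles <- function(path, kind = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- list()
  declared <- NULL
  for (h in hdr) {
    m <- regmatches(lines[h], regexec("^#\\s*([^:]+):\\s*(.*)$", lines[h]))[[1]]
    if (length(m) == 3) {
      key <- trimws(m[2])
      if (key == "kind") declared <- trimws(m[3]) else meta[[key]] <- trimws(m[3])
    }
  }
  if (is.null(declared)) {
    stop(sprintf("%s: header does not declare its kind", path), call. = FALSE)
  }
  if (!declared %in% names(.profile_specs)) {
    stop(sprintf("%s: unknown kind '%s'", path, declared), call. = FALSE)
  }
  if (!is.null(kind) && declared != kind) {
    stop(sprintf("%s: declared kind '%s', expected '%s'", path, declared, kind),
      call. = FALSE
    )
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  spec <- .profile_specs[[declared]]
  missing_cols <- setdiff(spec$required, names(df))
  if (length(missing_cols)) {
    stop(sprintf(
      "%s: missing required column(s): %s", path,
      paste(missing_cols, collapse = ", ")
    ), call. = FALSE)
  }
  for (cl in names(df)) {
    v <- df[[cl]]
    if (is.numeric(v)) next
    parsed <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(parsed))
    # all-character columns (labels, flags) are fine; a column that parses
    # only partly has malformed rows
    if (length(bad) && length(bad) < sum(!is.na(v))) {
      stop(sprintf(
        "%s: malformed value(s) in column '%s' at data row(s) %s", path, cl,
        paste(utils::head(bad, 5), collapse = ", ")
      ), call. = FALSE)
    }
  }
  if (!is.null(spec$monotone)) {
    d <- df[[spec$monotone]]
    if (any(diff(d) < 0)) {
      stop(sprintf("%s: column '%s' is not monotonically increasing", path, spec$monotone),
        call. = FALSE
      )
    }
  }
  attr(df, "kind") <- declared
  attr(df, "meta") <- meta
  df
}
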