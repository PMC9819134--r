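# Strict readers/writers. Interchange formats are deliberately plain:
# two-column CSV for chromatograms, TSV for every multi-column table
# (compound names contain commas and brackets). All numeric round-trips
# preserve at least 12 significant digits.

#' Read a chromatogram CSV
#'
#' Expects a two-column CSV with the exact header `rt,intensity`; retention
#' times in minutes, strictly increasing, at least 8 rows. Rejections are
#' total: no partially-constructed object escapes on error.
#'
#' @param path file path.
#' @param sample_id sample identifier; defaults to the filename stem.
#' @return A [chromatogram()].
#' @export
read_chromatogram <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "rt,intensity")
    stop_fmt("%s: expected header 'rt,intensity'", path)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad))
    stop_fmt("%s: line %d does not have two fields", path, bad[1] + 1L)
  rt <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 1L)))
  it <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 2L)))
  if (anyNA(rt) || anyNA(it)) {
    bad <- which(is.na(rt) | is.na(it))[1]
    stop_fmt("%s: non-numeric value on line %d", path, bad + 1L)
  }
  if (length(rt) < 8)
    stop_fmt("%s: %d data rows; at least 8 required", path, length(rt))
  if (any(diff(rt) <= 0))
    stop_fmt("%s: retention times not strictly increasing at line %d",
             path, which(diff(rt) <= 0)[1] + 2L)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  chromatogram(rt, it, sample_id)
}

#' Write a chromatogram CSV
#'
#' @param chrom a valid [chromatogram()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_chromatogram <- function(chrom, path) {
  validate_chromatogram(chrom)
  lines <- c("rt,intensity",
             paste(fmt_num(chrom$rt), fmt_num(chrom$intensity), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

.peak_table_cols <- c("sample_id", "rt", "height", "prominence", "width",
                      "left_rt", "right_rt", "area", "ratio", "confirmed")

#' Write / read a peak table TSV
#'
#' Columns `sample_id rt height prominence width left_rt right_rt area ratio
#' confirmed`; numeric fields round-trip to 12 significant digits and the
#' boolean flag exactly.
#'
#' @param peak_table a peak table ([detect_peaks()] output, or a row-bound
#'   set of them).
#' @param path file path.
#' @return `write_peak_table` returns `path` invisibly; `read_peak_table`
#'   returns a `peak_table` data.frame.
#' @export
write_peak_table <- function(peak_table, path) {
  df <- as.data.frame(peak_table)[, .peak_table_cols, drop = FALSE]
  num <- vapply(df, is.numeric, logical(1))
  for (cn in names(df)[num]) df[[cn]] <- fmt_num(df[[cn]])
  df$confirmed <- ifelse(as.logical(peak_table$confirmed), "true", "false")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  if (!identical(names(df), .peak_table_cols))
    stop_fmt("%s: expected columns '%s', found '%s'", path,
             paste(.peak_table_cols, collapse = " "),
             paste(names(df), collapse = " "))
  numcols <- setdiff(.peak_table_cols, c("sample_id", "confirmed"))
  for (cn in numcols) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    if (nrow(df) && anyNA(v))
      stop_fmt("%s: non-numeric '%s' value on line %d", path, cn,
               which(is.na(v))[1] + 1L)
    df[[cn]] <- v
  }
  if (nrow(df) && !all(df$confirmed %in% c("true", "false")))
    stop_fmt("%s: 'confirmed' must be true/false, found '%s'", path,
             setdiff(df$confirmed, c("true", "false"))[1])
  df$confirmed <- df$confirmed == "true"
  if (!nrow(df)) df$confirmed <- logical(0)
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Read a long-format covariate TSV
#'
#' Expects columns `sample_id covariate value`. Duplicate
#' `(sample_id, covariate)` pairs are an integrity error. Covariates whose
#' non-missing values all parse as numbers are flagged numeric (see the
#' `numeric_covariates` attribute); others are categorical.
#'
#' @param path file path.
#' @return A `covariate_table` data.frame (`sample_id`, `covariate`,
#'   `value` as character) with attribute `numeric_covariates`.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          colClasses = "character")
  need <- c("sample_id", "covariate", "value")
  if (!identical(names(df), need))
    stop_fmt("%s: expected columns '%s'", path, paste(need, collapse = " "))
  key <- paste(df$sample_id, df$covariate, sep = "\r")
  if (anyDuplicated(key))
    stop_fmt("%s: duplicate (sample_id, covariate) pair on line %d", path,
             which(duplicated(key))[1] + 1L)
  numeric_cov <- vapply(unique(df$covariate), function(cov) {
    v <- df$value[df$covariate == cov]
    v <- v[!is.na(v) & v != ""]
    length(v) > 0 && !anyNA(suppressWarnings(as.numeric(v)))
  }, logical(1))
  structure(df, numeric_covariates = names(numeric_cov)[numeric_cov],
            class = c("covariate_table", "data.frame"))
}

#' Write / read a labels TSV (`sample_id`, `label`)
#'
#' @param labels named integer vector (names = sample ids).
#' @param path file path.
#' @return `write_labels` returns `path` invisibly; `read_labels` a named
#'   integer vector.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(sample_id = names(labels),
                                label = as.integer(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  stats::setNames(as.integer(df$label), df$sample_id)
}

#' Write / read a profile matrix TSV (`sample_id f0 ... f9`)
#'
#' @param m a `profile_matrix`.
#' @param path file path.
#' @return `write_profiles` returns `path` invisibly; `read_profiles` a
#'   `profile_matrix` (standardization flag restored from the file's
#'   comment line).
#' @export
write_profiles <- function(m, path) {
  hdr <- sprintf("# standardized: %s",
                 if (isTRUE(attr(m, "standardized"))) "true" else "false")
  df <- data.frame(sample_id = rownames(m),
                   apply(m, 2, fmt_num), check.names = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  first <- readLines(path, n = 1L)
  std <- identical(first, "# standardized: true")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  structure(m, standardized = std,
            class = c("profile_matrix", "matrix", "array"))
}

#' Write / read a compound table TSV (`sample_id compound_name rt`)
#'
#' @param compounds data.frame `sample_id`, `compound_name`, `rt`.
#' @param path file path.
#' @return `write_compounds` returns `path` invisibly; `read_compounds` the
#'   data.frame.
#' @export
write_compounds <- function(compounds, path) {
  df <- compounds
  df$rt <- fmt_num(df$rt)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_compounds
#' @export
read_compounds <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  df$rt <- as.numeric(df$rt)
  df
}
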