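# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
extdata_path <- function(file) {
  path <- system.file("extdata", file, package = "dietexposome")
  if (!nzchar(path)) stop("packaged data file not found: ", file, call. = FALSE)
  path
}

# read.csv wrapper: UTF-8, no factors, empty string -> NA for character cols
read_csv_strict <- function(path, required_header) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        fileEncoding = "UTF-8", colClasses = "character")
  if (!identical(names(df), required_header)) {
    stop("unexpected CSV header in ", path,
         "\n  expected: ", paste(required_header, collapse = ","),
         "\n  found:    ", paste(names(df), collapse = ","), call. = FALSE)
  }
  df[df == ""] <- NA
  df
}

# numeric parse with row/column error reporting (1-based data rows)
parse_num_col <- function(x, col, allow_na = TRUE) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop("malformed numeric value in column '", col, "', row ", bad[1],
         ": '", x[bad[1]], "'", call. = FALSE)
  }
  if (!allow_na && anyNA(out)) {
    stop("missing value in required column '", col, "', row ",
         which(is.na(out))[1], call. = FALSE)
  }
  out
}

check_enum_col <- function(x, col, levels, allow_na = FALSE) {
  bad <- which(!(x %in% levels) & !(allow_na & is.na(x)))
  if (length(bad)) {
    stop("invalid value in column '", col, "', row ", bad[1], ": '",
         x[bad[1]], "' (allowed: ", paste(levels, collapse = ", "), ")",
         call. = FALSE)
  }
  invisible(x)
}

# full-precision-enough numeric formatting for CSV round trips
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.12g", v)
  }, character(1))
  out
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = TRUE,
                   fileEncoding = "UTF-8")
}
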