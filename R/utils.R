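#' Min-max rescale a numeric vector to [0, 1]
#'
#' Maps the smallest value to 0 and the largest to 1. When all values are
#' identical the scale is undefined; every value is then set to 0 and a
#' warning is emitted, so that a completely uninformative score channel
#' contributes nothing downstream.
#'
#' @param x Numeric vector, no NAs.
#' @return Numeric vector of the same length in [0, 1].
#' @export
minmax_normalize <- function(x) {
  stopifnot(is.numeric(x), !anyNA(x))
  if (length(x) == 0L) return(numeric(0))
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("all values identical; normalized scores set to 0")
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

# canonical internal key: uppercased, whitespace-free symbol
as_symbol <- function(x) {
  x <- toupper(trimws(as.character(x)))
  if (any(grepl("\\s", x))) stop("gene symbols must not contain whitespace")
  x
}

# read a TSV with no header, enforcing a column count; errors name the line
read_tsv_cols <- function(path, n_cols, col_names, header = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (header && length(lines) > 0L) lines <- lines[-1L]
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    out <- as.data.frame(matrix(character(0), ncol = n_cols))
    names(out) <- col_names
    return(tibble::as_tibble(out))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_cols)
  if (length(bad) > 0L) {
    stop(sprintf("malformed row at line %d of '%s': expected %d tab-separated columns, found %d",
                 bad[1] + as.integer(header), path, n_cols, lengths(parts)[bad[1]]))
  }
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- col_names
  tibble::as_tibble(out)
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
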