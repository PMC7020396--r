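# Internal helpers shared across modules.

# Tokens accepted as missing values in numeric columns of the tab-delimited
# inputs (TASSEL writes "NaN"; hand-edited files often use "NA" or blanks).
.missing_tokens <- c("NA", "NaN", "")

# Locale-independent ordering (C collation) so rankings and tie-breaks are
# byte-identical across machines.
radix_order <- function(...) order(..., method = "radix")

#' @noRd
#' Parse a character column to numeric, distinguishing accepted missing
#' tokens (-> NA, kept) from unparseable garbage (-> rejected rows).
#' Returns list(values = numeric, bad = logical index of unparseable cells).
parse_numeric_cells <- function(x, column) {
  x <- trimws(as.character(x))
  is_missing <- x %in% .missing_tokens | is.na(x)
  values <- suppressWarnings(as.numeric(x))
  bad <- is.na(values) & !is_missing
  values[is_missing] <- NA_real_
  if (any(bad)) {
    warning(sprintf("%d row(s) with unreadable numeric value in column '%s' rejected",
                    sum(bad), column), call. = FALSE)
  }
  list(values = values, bad = bad)
}

#' @noRd
#' read.delim wrapper: tab-separated, everything as character, no name
#' mangling. Base file() auto-detects gzip, so .gz inputs work transparently.
read_tsv_chr <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE,
                    na.strings = NULL)
}

#' @noRd
require_columns <- function(df, needed, path) {
  missing <- setdiff(unname(needed), names(df))
  if (length(missing) > 0) {
    stop(sprintf("file '%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' @noRd
#' Derive one RNG seed per bootstrap replicate from the master seed so that
#' results are independent of how replicates are split across workers.
replicate_seeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}
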