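#' Round half away from zero to the nearest integer
#'
#' Presentation rounding for cohort percentages: exact halves round up
#' (half-up), unlike [base::round()]'s round-half-to-even.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @keywords internal
round_half_up <- function(x) {
  floor(x + 0.5)
}

#' Read a delimited table, sniffing the separator
#'
#' Accepts TSV or CSV with a header row. The separator is taken from the
#' file extension (`.csv` vs anything else), falling back to a tab.
#'
#' @param path File path.
#' @return A data.frame with character columns left unconverted.
#' @keywords internal
read_delim_table <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "", na.strings = c("NA", ""))
}

#' Write a data.frame as TSV
#' @keywords internal
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Require named columns in a data.frame, with a format error naming the
# first missing one.
check_columns <- function(df, required, what = "table") {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

# Spawn a stream of child seeds from a master seed. Simple documented
# counter scheme: child i is (master * 1000 + i) mod 2^31 - 1, kept in
# 32-bit integer range.
spawn_seeds <- function(master_seed, n) {
  as.integer((as.numeric(master_seed) * 1000 + seq_len(n)) %% 2147483647)
}
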