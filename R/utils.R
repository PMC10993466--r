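#' Round half away from zero
#'
#' Printed percentages in the summary tables use commercial rounding
#' (half away from zero), not the IEEE banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(0.5)   # 1, where round(0.5) is 0
#' round_half_away(83.908, 1)
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Percentage of a count over a denominator
#'
#' @param num numerator count.
#' @param den denominator count.
#' @param digits decimal places (half-away-from-zero rounding).
#' @return numeric percentage, `NA` when `den` is 0.
#' @export
#' @examples
#' pct(1497, 7432, 2)  # 20.14
pct <- function(num, den, digits = 1) {
  out <- round_half_away(100 * num / den, digits)
  out[rep_len(den, length(out)) == 0] <- NA_real_
  out
}

## strict TSV reader: tab-separated, header, no quoting games
read_tsv_strict <- function(path, required = NULL, what = "table") {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""), quote = "",
                          comment.char = "")
  if (!is.null(required)) {
    miss <- setdiff(required, names(df))
    if (length(miss) > 0) {
      stop(sprintf("%s is missing required column(s): %s", what,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  df
}

#' Write a data frame as TSV
#'
#' Canonical tab-separated output used by all exporters: no quoting,
#' no row names, `NA` literal for missing values.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

DNA_BASES <- c("A", "C", "G", "T")

is_acgt <- function(x) x %in% DNA_BASES

## stable variant key used across modules
variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}
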