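#' Round half away from zero
#'
#' Standard commercial rounding: 0.5 always rounds away from zero, unlike
#' [base::round()]'s round-half-even. Used for every reported percentage so
#' printed tables are reproduced digit for digit.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_away(90.625, 1)  # 90.6
#' round_half_away(12.5)       # 13
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * trunc(abs(x) * m + 0.5) / m
}

# Derive a child seed from a master seed and an integer salt, staying within
# the 32-bit signed range R requires for set.seed().
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(salt) * 104729) %% 2147483587L)
}

write_tsv0 <- function(df, path, header_comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv0 <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
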