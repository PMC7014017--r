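#' Round half away from zero
#'
#' Base [round()] uses banker's rounding (round-half-to-even); census
#' summary tables are printed with conventional half-up rounding, so all
#' derived statistics go through this helper.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return numeric vector rounded half-up to `digits` places.
#' @examples
#' round_half_up(0.5)        # 1, where round(0.5) is 0
#' round_half_up(6.754)      # 7
#' round_half_up(0.085, 2)   # 0.09
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # nudge by an ulp-scale epsilon so values like 0.085 stored as
  # 0.08499999... still round up
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

#' @noRd
stop_cyp <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "cypcensus_error")))
}

#' @noRd
assert_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop_cyp(what, " must be a non-empty string", class = "cyp_input_error")
  }
  invisible(x)
}

# Residues accepted in candidate sequences: the 20 standard amino acids
# plus X (unknown).
AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' @noRd
assert_aa_sequence <- function(seq, what = "sequence") {
  assert_scalar_chr(seq, what)
  bad <- setdiff(unique(strsplit(seq, "", fixed = TRUE)[[1]]),
                 c(AA_STANDARD, "X"))
  if (length(bad)) {
    stop_cyp(what, " contains non-residue characters: ",
             paste(bad, collapse = ", "), class = "cyp_input_error")
  }
  invisible(seq)
}

#' Write a data frame as tab-separated text
#'
#' All pipeline outputs are plain TSV so they diff cleanly and re-read
#' without loss. Row names are never written.
#'
#' @param df data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop_cyp("cannot write ", path,
                                               class = "cyp_io_error"))
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Read a tab-separated file written by the pipeline
#'
#' @param path file path.
#' @return data frame with character columns left unconverted.
#' @export
read_tsv_file <- function(path) {
  if (!file.exists(path)) {
    stop_cyp("input file does not exist: ", path, class = "cyp_io_error")
  }
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = NULL)
}
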