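#' Scoring scheme for global protein alignment
#'
#' Classification rests entirely on percent identity from deterministic
#' global (Needleman–Wunsch) alignment. The default scheme is BLOSUM62 with
#' affine gap penalties: a gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param matrix_name substitution matrix name (any matrix shipped with
#'   Biostrings, e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`).
#' @param gap_open non-negative gap opening penalty (default 10).
#' @param gap_extend non-negative per-residue gap extension penalty
#'   (default 1).
#' @param identity_denominator how the identity denominator is defined:
#'   `"trimmed_columns"` (default) counts aligned columns after trimming
#'   terminal-gap columns, internal gap columns included;
#'   `"shorter_sequence"` divides by the length of the shorter input.
#' @return a `scoring_scheme` list.
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62",
                           gap_open = 10, gap_extend = 1,
                           identity_denominator = c("trimmed_columns",
                                                    "shorter_sequence")) {
  stopifnot(gap_open >= 0, gap_extend >= 0)
  identity_denominator <- match.arg(identity_denominator)
  mat <- get_substitution_matrix(matrix_name)
  if (!isTRUE(all.equal(mat, t(mat)))) {
    stop_cyp("substitution matrix ", matrix_name, " is not symmetric",
             class = "cyp_config_error")
  }
  structure(list(matrix_name = matrix_name,
                 matrix = mat,
                 gap_open = gap_open,
                 gap_extend = gap_extend,
                 identity_denominator = identity_denominator),
            class = "scoring_scheme")
}

#' @noRd
get_substitution_matrix <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e)) {
    stop_cyp("unknown substitution matrix: ", name,
             class = "cyp_config_error")
  }
  get(name, envir = e)
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman–Wunsch alignment with affine gaps under the given scheme
#' (terminal gaps are penalized). The dynamic programming is done by
#' `Biostrings::pairwiseAlignment`; the result is repackaged with the
#' percent identity under the scheme's denominator definition.
#'
#' @param a,b amino-acid sequences (non-empty; standard residues plus X).
#' @param scheme a [scoring_scheme()].
#' @return an `alignment_result` list with `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, and `identity_percent`.
#' @examples
#' global_align("ACDEF", "ACF")$identity_percent  # 60
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  assert_aa_sequence(a, "sequence a")
  assert_aa_sequence(b, "sequence b")
  stopifnot(inherits(scheme, "scoring_scheme"))
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend,
    type = "global")
  aligned_a <- as.character(Biostrings::alignedPattern(pa))
  aligned_b <- as.character(Biostrings::alignedSubject(pa))
  res <- structure(list(aligned_a = unname(aligned_a),
                        aligned_b = unname(aligned_b),
                        score = Biostrings::score(pa),
                        identity_percent = NA_real_),
                   class = "alignment_result")
  res$identity_percent <- percent_identity(res, scheme = scheme,
                                           a = a, b = b)
  res
}

#' Percent identity of an alignment
#'
#' Identity is `100 * identical columns / denominator`. Under the default
#' `"trimmed_columns"` definition the denominator is the number of aligned
#' columns after terminal-gap columns are trimmed from both ends (internal
#' gap columns still count); this approximates the identity a local
#' aligner reports for near-full-length homologs while keeping the
#' alignment global. Under `"shorter_sequence"` the denominator is the
#' length of the shorter input sequence.
#'
#' @param alignment an `alignment_result` from [global_align()].
#' @param scheme the [scoring_scheme()] (carries the denominator choice).
#' @param a,b the original ungapped sequences; only needed for the
#'   `"shorter_sequence"` denominator, recovered from the alignment when
#'   omitted.
#' @return identity percentage in \[0, 100\].
#' @export
percent_identity <- function(alignment, scheme = scoring_scheme(),
                             a = NULL, b = NULL) {
  ca <- strsplit(alignment$aligned_a, "", fixed = TRUE)[[1]]
  cb <- strsplit(alignment$aligned_b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  gap <- ca == "-" | cb == "-"
  nongap <- which(!gap)
  if (length(nongap) == 0L) {
    stop_cyp("alignment has no aligned residue columns; identity undefined",
             class = "cyp_domain_error")
  }
  keep <- seq(min(nongap), max(nongap))  # trim terminal-gap columns
  matches <- sum(ca[keep] == cb[keep] & ca[keep] != "-")
  denom <- switch(scheme$identity_denominator,
    trimmed_columns = length(keep),
    shorter_sequence = {
      if (is.null(a)) a <- gsub("-", "", alignment$aligned_a, fixed = TRUE)
      if (is.null(b)) b <- gsub("-", "", alignment$aligned_b, fixed = TRUE)
      min(nchar(a), nchar(b))
    })
  100 * matches / denom
}

#' Rank reference P450s by identity to a query
#'
#' Globally aligns the query against every reference and returns the full
#' ranking, sorted by descending identity with ties broken by ascending
#' reference label. The classifier consumes rank 1 (the named homolog).
#'
#' @param query amino-acid sequence.
#' @param refdb a [reference_db()].
#' @param scheme a [scoring_scheme()].
#' @return data frame with columns `ref_name`, `identity_percent`, `score`,
#'   one row per reference, best first.
#' @export
best_hits <- function(query, refdb, scheme = scoring_scheme()) {
  stopifnot(inherits(refdb, "reference_db"))
  if (nrow(refdb$entries) == 0L) {
    stop_cyp("reference database is empty", class = "cyp_config_error")
  }
  alns <- lapply(refdb$entries$sequence, function(s)
    global_align(query, s, scheme))
  out <- data.frame(ref_name = refdb$entries$name,
                    identity_percent = vapply(alns, `[[`, 0, "identity_percent"),
                    score = vapply(alns, `[[`, 0, "score"),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$identity_percent, out$ref_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
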