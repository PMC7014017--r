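#' Triage parameters
#'
#' Candidate proteins are partitioned into full-length P450s, P450
#' fragments, and false positives before any classification. The rules are
#' this package's own convention (superfamily membership in the source
#' studies came from an external domain search): a candidate must carry the
#' P450 heme-binding motif, F-x-x-G-x-x-x-C-x-G, whose invariant cysteine
#' ligates the heme iron; motif-bearing candidates shorter than
#' `min_full_length` are fragments; candidates without the motif are false
#' positives. An optional second check requires the conserved E-x-x-R salt
#' bridge motif of the K-helix.
#'
#' @param min_full_length minimum amino-acid length of a full-length P450
#'   (default 300; typical bacterial P450s run ~400 aa).
#' @param heme_pattern regular expression for the heme motif.
#' @param require_exxr also require the E-x-x-R motif (default `FALSE`).
#' @return a `triage_params` list.
#' @export
triage_params <- function(min_full_length = 300L,
                          heme_pattern = "F..G...C.G",
                          require_exxr = FALSE) {
  stopifnot(is.numeric(min_full_length), min_full_length > 0)
  structure(list(min_full_length = as.integer(min_full_length),
                 heme_pattern = heme_pattern,
                 require_exxr = isTRUE(require_exxr)),
            class = "triage_params")
}

#' Triage one candidate protein
#'
#' @param sequence amino-acid sequence (20 standard residues plus X).
#' @param params a [triage_params()] object.
#' @return list with `category` (`"full_length"`, `"fragment"` or
#'   `"false_positive"`) and `reasons`, the identifiers of every rule that
#'   fired.
#' @examples
#' p <- triage_params()
#' triage_candidate(paste0(strrep("A", 440), "FGAGRHRCIG"), p)$category
#' @export
triage_candidate <- function(sequence, params = triage_params()) {
  assert_aa_sequence(sequence)
  stopifnot(inherits(params, "triage_params"))
  reasons <- character(0)
  has_heme <- grepl(params$heme_pattern, sequence)
  has_exxr <- !params$require_exxr || grepl("E..R", sequence)
  if (!has_heme) reasons <- c(reasons, "no_heme_motif")
  if (!has_exxr) reasons <- c(reasons, "no_exxr_motif")
  short <- nchar(sequence) < params$min_full_length
  if (short) reasons <- c(reasons, "below_min_length")
  category <- if (!has_heme || !has_exxr) {
    "false_positive"
  } else if (short) {
    "fragment"
  } else {
    "full_length"
  }
  list(category = category, reasons = reasons)
}

#' Triage a whole proteome
#'
#' Applies [triage_candidate()] to every record and returns the three-way
#' partition plus summary counts. Only `full_length` records should flow on
#' to classification.
#'
#' @param records data frame with columns `protein_id`, `species_id`,
#'   `sequence`.
#' @param params a [triage_params()] object.
#' @return list with `records` (the input plus `category` and `reasons`
#'   columns), `full_length`, `fragment`, `false_positive` (row subsets) and
#'   `counts`, a named integer vector summing to `nrow(records)`.
#' @export
triage_proteome <- function(records, params = triage_params()) {
  stopifnot(is.data.frame(records),
            all(c("protein_id", "species_id", "sequence") %in% names(records)))
  dup <- records$protein_id[duplicated(records$protein_id)]
  if (length(dup)) {
    stop_cyp("duplicate protein_id in proteome: ",
             paste(unique(dup), collapse = ", "), class = "cyp_input_error")
  }
  if (nrow(records) == 0L) {
    out <- cbind(records, category = character(0), reasons = character(0))
    return(list(records = out,
                full_length = out, fragment = out, false_positive = out,
                counts = c(full_length = 0L, fragment = 0L,
                           false_positive = 0L)))
  }
  res <- lapply(records$sequence, triage_candidate, params = params)
  records$category <- vapply(res, `[[`, "", "category")
  records$reasons <- vapply(res, function(r) paste(r$reasons, collapse = ";"), "")
  parts <- split(records, factor(records$category,
                                 levels = c("full_length", "fragment",
                                            "false_positive")))
  counts <- vapply(parts, nrow, 0L)
  list(records = records,
       full_length = parts$full_length,
       fragment = parts$fragment,
       false_positive = parts$false_positive,
       counts = counts)
}
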