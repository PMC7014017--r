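#' Reference database of named P450s
#'
#' The classifier measures each candidate against named homologs. The
#' database is a set of (CYP label, sequence) pairs; labels must be
#' well-formed, unique, and parseable by [parse_p450_name()].
#'
#' @param names character vector of CYP labels.
#' @param sequences character vector of amino-acid sequences.
#' @return a `reference_db` with an `entries` data frame (columns `name`,
#'   `sequence`, `family`, `subfamily`).
#' @export
reference_db <- function(names, sequences) {
  stopifnot(length(names) == length(sequences))
  if (anyDuplicated(names)) {
    stop_cyp("duplicate reference names: ",
             paste(unique(names[duplicated(names)]), collapse = ", "),
             class = "cyp_config_error")
  }
  parsed <- lapply(names, parse_p450_name)
  for (s in sequences) assert_aa_sequence(s, "reference sequence")
  entries <- data.frame(
    name = names,
    sequence = sequences,
    family = vapply(parsed, family_token, ""),
    subfamily = vapply(parsed, subfamily_token, ""),
    stringsAsFactors = FALSE)
  structure(list(entries = entries), class = "reference_db")
}

#' Read a reference database from FASTA
#'
#' Headers are `><label> <free text>`; the first whitespace-delimited token
#' is the CYP label.
#'
#' @param path FASTA file of named reference P450s.
#' @return a [reference_db()].
#' @export
read_reference_db <- function(path) {
  if (!file.exists(path)) {
    stop_cyp("reference FASTA not found: ", path, class = "cyp_io_error")
  }
  aa <- Biostrings::readAAStringSet(path)
  labels <- vapply(strsplit(names(aa), "\\s+"), `[[`, "", 1L)
  reference_db(labels, as.character(aa))
}

#' Write a reference database to FASTA
#' @param refdb a [reference_db()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reference_db <- function(refdb, path) {
  stopifnot(inherits(refdb, "reference_db"))
  aa <- Biostrings::AAStringSet(refdb$entries$sequence)
  names(aa) <- refdb$entries$name
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(aa, path, width = 70L)
  invisible(path)
}

#' Nomenclature thresholds
#'
#' Family and subfamily membership follow the International P450
#' Nomenclature Committee convention: identity strictly greater than the
#' family threshold (40%) places a protein in its best hit's family;
#' strictly greater than the subfamily threshold (55%) places it in the
#' best hit's subfamily. Values exactly at a threshold fall to the lower
#' category; set `inclusive = TRUE` to use `>=` comparisons instead.
#'
#' @param family family threshold in percent (default 40).
#' @param subfamily subfamily threshold in percent (default 55).
#' @param inclusive use `>=` instead of `>` at the boundaries.
#' @return a `cyp_thresholds` list.
#' @export
cyp_thresholds <- function(family = 40, subfamily = 55, inclusive = FALSE) {
  if (!(family < subfamily)) {
    stop_cyp("family threshold must be below subfamily threshold",
             class = "cyp_config_error")
  }
  structure(list(family = family, subfamily = subfamily,
                 inclusive = isTRUE(inclusive)),
            class = "cyp_thresholds")
}

#' @noRd
status_from_identity <- function(identity, thresholds) {
  above <- function(x, t) if (thresholds$inclusive) x >= t else x > t
  if (above(identity, thresholds$subfamily)) {
    "known_subfamily"
  } else if (above(identity, thresholds$family)) {
    "new_subfamily_in_family"
  } else {
    "new_family"
  }
}

#' Assign family and subfamily to one candidate
#'
#' The candidate is aligned against every reference; the single best hit
#' (ties broken alphabetically) determines the assignment. Identity above
#' the subfamily threshold inherits the hit's subfamily; identity between
#' the two thresholds inherits the hit's family and receives a provisional
#' new subfamily; identity at or below the family threshold founds a
#' provisional new family.
#'
#' @param protein_id candidate identifier.
#' @param sequence amino-acid sequence (should have passed triage as
#'   full length).
#' @param refdb a [reference_db()].
#' @param thresholds a [cyp_thresholds()].
#' @param scheme a [scoring_scheme()].
#' @param registry a [provisional_registry()] used to mint provisional
#'   labels; a fresh one is used when omitted.
#' @return an `assignment_result` list: `protein_id`, `best_hit_name`,
#'   `identity_percent`, `status`, `assigned_family`, `assigned_subfamily`.
#' @export
assign_p450 <- function(protein_id, sequence, refdb,
                        thresholds = cyp_thresholds(),
                        scheme = scoring_scheme(),
                        registry = provisional_registry()) {
  hits <- best_hits(sequence, refdb, scheme)
  top <- hits[1L, ]
  status <- status_from_identity(top$identity_percent, thresholds)
  hit_parsed <- parse_p450_name(top$ref_name)
  fam <- family_token(hit_parsed)
  subfam <- subfamily_token(hit_parsed)
  if (status == "known_subfamily") {
    # a family-level reference (no subfamily letters) cannot donate a
    # subfamily; mint a provisional one inside its family
    if (is.na(subfam)) {
      subfam <- allocate_provisional(registry, "new_subfamily", fam)
      status <- "new_subfamily_in_family"
    }
    assigned_family <- fam
    assigned_subfamily <- subfam
  } else if (status == "new_subfamily_in_family") {
    assigned_family <- fam
    assigned_subfamily <- allocate_provisional(registry, "new_subfamily", fam)
  } else {
    assigned_family <- allocate_provisional(registry, "new_family")
    assigned_subfamily <- paste0(assigned_family, "_NS1")
  }
  structure(list(protein_id = protein_id,
                 best_hit_name = top$ref_name,
                 identity_percent = top$identity_percent,
                 status = status,
                 assigned_family = assigned_family,
                 assigned_subfamily = assigned_subfamily),
            class = "assignment_result")
}

#' Classify a triaged proteome
#'
#' Runs [assign_p450()] over every record in sorted `protein_id` order (so
#' provisional ordinals are reproducible run to run) and returns one row
#' per record plus per-species tallies.
#'
#' @param records data frame with `protein_id`, `species_id`, `sequence`
#'   columns (the `full_length` partition from [triage_proteome()]).
#' @param refdb a [reference_db()].
#' @param thresholds a [cyp_thresholds()].
#' @param scheme a [scoring_scheme()].
#' @return list with `assignments` (data frame: `protein_id`, `species_id`,
#'   `best_hit`, `identity_percent`, `status`, `family`, `subfamily`) and
#'   `species_tally` (data frame of per-species P450 counts).
#' @export
classify_proteome <- function(records, refdb,
                              thresholds = cyp_thresholds(),
                              scheme = scoring_scheme()) {
  stopifnot(is.data.frame(records),
            all(c("protein_id", "species_id", "sequence") %in% names(records)))
  records <- records[order(records$protein_id), , drop = FALSE]
  registry <- provisional_registry()
  rows <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    a <- tryCatch(
      assign_p450(records$protein_id[i], records$sequence[i], refdb,
                  thresholds, scheme, registry),
      error = function(e) {
        stop_cyp("classification failed for protein '",
                 records$protein_id[i], "': ", conditionMessage(e),
                 class = "cyp_classify_error")
      })
    rows[[i]] <- data.frame(protein_id = a$protein_id,
                            species_id = records$species_id[i],
                            best_hit = a$best_hit_name,
                            identity_percent = a$identity_percent,
                            status = a$status,
                            family = a$assigned_family,
                            subfamily = a$assigned_subfamily,
                            stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(assignments)) {
    assignments <- data.frame(protein_id = character(0),
                              species_id = character(0),
                              best_hit = character(0),
                              identity_percent = numeric(0),
                              status = character(0),
                              family = character(0),
                              subfamily = character(0))
  }
  tally <- as.data.frame(table(species_id = assignments$species_id),
                         stringsAsFactors = FALSE)
  names(tally) <- c("species_id", "n_p450")
  list(assignments = assignments, species_tally = tally)
}
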