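#' Parse a CYP nomenclature label
#'
#' Cytochrome P450s are named `CYP<family number><subfamily letters><protein
#' number>`: a positive integer family, zero to two uppercase subfamily
#' letters, and an optional protein number (e.g. `CYP110C17` is protein 17
#' of subfamily C of family 110; `CYP51` is a family-level label with no
#' subfamily). Subfamily letters are taken greedily as the longest run of
#' uppercase letters between the family number and the trailing protein
#' number, so double-letter subfamilies such as `CYP110AH1` parse as
#' subfamily "AH".
#'
#' @param label a single CYP label string.
#' @return an object of class `p450_name`: a list with `raw_label`,
#'   `family_number`, `subfamily_letters` (`""` when absent) and
#'   `protein_number` (`NA` when absent).
#' @examples
#' parse_p450_name("CYP110C17")
#' parse_p450_name("CYP1011G1")
#' @export
parse_p450_name <- function(label) {
  assert_scalar_chr(label, "label")
  m <- regexec("^CYP([0-9]+)([A-Z]*)([0-9]*)$", label)
  parts <- regmatches(label, m)[[1]]
  if (length(parts) == 0L) {
    stop_cyp("malformed P450 label: '", label,
             "' (expected CYP<family><subfamily letters><protein number>)",
             class = "cyp_parse_error")
  }
  letters_part <- parts[3]
  if (nchar(letters_part) > 2L) {
    stop_cyp("malformed P450 label: '", label,
             "' (subfamily letter run '", letters_part,
             "' longer than 2 characters)", class = "cyp_parse_error")
  }
  fam <- as.integer(parts[2])
  if (is.na(fam) || fam < 1L) {
    stop_cyp("malformed P450 label: '", label, "' (no family number)",
             class = "cyp_parse_error")
  }
  prot <- if (nzchar(parts[4])) as.integer(parts[4]) else NA_integer_
  if (!is.na(prot) && prot < 1L) {
    stop_cyp("malformed P450 label: '", label, "' (protein number must be >= 1)",
             class = "cyp_parse_error")
  }
  structure(list(raw_label = label,
                 family_number = fam,
                 subfamily_letters = letters_part,
                 protein_number = prot),
            class = "p450_name")
}

#' @export
print.p450_name <- function(x, ...) {
  cat("<p450_name> ", render_p450_name(x),
      " (family ", x$family_number,
      if (nzchar(x$subfamily_letters)) paste0(", subfamily ", x$subfamily_letters),
      if (!is.na(x$protein_number)) paste0(", protein ", x$protein_number),
      ")\n", sep = "")
  invisible(x)
}

#' Render a parsed P450 name back to its label
#'
#' Inverse of [parse_p450_name()]: well-formed labels round-trip exactly.
#'
#' @param name a `p450_name`.
#' @return the label string.
#' @export
render_p450_name <- function(name) {
  stopifnot(inherits(name, "p450_name"))
  paste0("CYP", name$family_number, name$subfamily_letters,
         if (!is.na(name$protein_number)) name$protein_number else "")
}

#' Family and subfamily tokens of a P450 name
#'
#' The family token is `CYP<family number>` and the subfamily token appends
#' the subfamily letters (`CYP110C`). These tokens key the census tables.
#'
#' @param name a `p450_name` (or a label string, parsed on the fly).
#' @return token string. `subfamily_token()` returns `NA_character_` when
#'   the name carries no subfamily letters.
#' @examples
#' family_token("CYP110AH1")     # "CYP110"
#' subfamily_token("CYP110AH1")  # "CYP110AH"
#' subfamily_token("CYP51")      # NA: family-level label
#' @export
family_token <- function(name) {
  if (is.character(name)) name <- parse_p450_name(name)
  stopifnot(inherits(name, "p450_name"))
  paste0("CYP", name$family_number)
}

#' @rdname family_token
#' @export
subfamily_token <- function(name) {
  if (is.character(name)) name <- parse_p450_name(name)
  stopifnot(inherits(name, "p450_name"))
  if (!nzchar(name$subfamily_letters)) return(NA_character_)
  paste0("CYP", name$family_number, name$subfamily_letters)
}

#' Registry of provisional family/subfamily identifiers
#'
#' Official CYP numbers are assigned by the International P450 Nomenclature
#' Committee; a census run cannot mint them. Candidates falling below the
#' family threshold (or landing in a family without a matching subfamily)
#' receive provisional placeholders instead: `CYP_NF<n>` for the n-th new
#' family of a run and `<family>_NS<n>` for the n-th new subfamily within a
#' given family. The reserved `_NF`/`_NS` infix guarantees a provisional
#' label can never collide with a well-formed CYP label.
#'
#' @return a `provisional_registry` (mutable environment).
#' @examples
#' reg <- provisional_registry()
#' allocate_provisional(reg, "new_family")             # "CYP_NF1"
#' allocate_provisional(reg, "new_subfamily", "CYP110") # "CYP110_NS1"
#' @export
provisional_registry <- function() {
  env <- new.env(parent = emptyenv())
  env$new_family <- 0L
  env$new_subfamily <- list()
  structure(env, class = "provisional_registry")
}

#' @rdname provisional_registry
#' @param registry a `provisional_registry`.
#' @param kind `"new_family"` or `"new_subfamily"`.
#' @param family family token scoping a new-subfamily allocation
#'   (required when `kind = "new_subfamily"`).
#' @export
allocate_provisional <- function(registry, kind = c("new_family", "new_subfamily"),
                                 family = NULL) {
  stopifnot(inherits(registry, "provisional_registry"))
  kind <- match.arg(kind)
  if (kind == "new_family") {
    registry$new_family <- registry$new_family + 1L
    paste0("CYP_NF", registry$new_family)
  } else {
    assert_scalar_chr(family, "family")
    n <- registry$new_subfamily[[family]]
    n <- if (is.null(n)) 1L else n + 1L
    registry$new_subfamily[[family]] <- n
    paste0(family, "_NS", n)
  }
}
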