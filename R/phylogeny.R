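#' Identity-based distance matrix
#'
#' Pairwise distances `d(a,b) = 1 - identity(a,b)/100` from global
#' alignment of every sequence pair — the substrate for the
#' neighbor-joining sanity tree. Symmetric with a zero diagonal; entries
#' lie in \[0, 1\].
#'
#' @param sequences named character vector of amino-acid sequences
#'   (>= 3, unique names).
#' @param scheme a [scoring_scheme()].
#' @return symmetric numeric matrix with the sequence names as dimnames.
#' @export
distance_matrix <- function(sequences, scheme = scoring_scheme()) {
  labels <- names(sequences)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop_cyp("sequences must be named", class = "cyp_input_error")
  }
  if (anyDuplicated(labels)) {
    stop_cyp("duplicate sequence labels: ",
             paste(unique(labels[duplicated(labels)]), collapse = ", "),
             class = "cyp_input_error")
  }
  n <- length(sequences)
  if (n < 3L) {
    stop_cyp("need at least 3 sequences for a distance matrix",
             class = "cyp_input_error")
  }
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      id <- global_align(sequences[[i]], sequences[[j]], scheme)$identity_percent
      d[i, j] <- d[j, i] <- 1 - id / 100
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (via `ape::nj`) on a validated
#' distance matrix; rows are sorted by label first so the result does not
#' depend on input order. On an additive matrix NJ recovers the generating
#' topology and branch lengths exactly.
#'
#' @param d symmetric non-negative distance matrix with labels as
#'   dimnames.
#' @return an unrooted `phylo` tree (ape) with branch lengths.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d))
  if (is.null(rownames(d)) || !identical(rownames(d), colnames(d))) {
    stop_cyp("distance matrix must have matching row/column labels",
             class = "cyp_input_error")
  }
  if (max(abs(d - t(d))) > 1e-9) {
    stop_cyp("distance matrix is not symmetric", class = "cyp_input_error")
  }
  if (any(d < 0)) {
    stop_cyp("distance matrix has negative entries", class = "cyp_input_error")
  }
  ord <- order(rownames(d))
  ape::nj(d[ord, ord])
}

#' Write a tree as Newick
#' @param tree a `phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Fraction of families that are monophyletic on a tree
#'
#' A correctness check on family assignment: on a well-resolved tree,
#' members of the same P450 family should group together. A family is
#' monophyletic on the unrooted tree when some bipartition (edge split)
#' separates exactly its members from everything else. Singleton families
#' are trivially monophyletic and are excluded from the denominator.
#'
#' @param tree a `phylo` whose tip labels all appear in `families`.
#' @param families named character vector: tip label -> family token.
#' @return fraction in \[0, 1\] of multi-member families that are
#'   monophyletic; `NA` when there is no multi-member family.
#' @export
family_grouping_score <- function(tree, families) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  missing <- setdiff(tips, names(families))
  if (length(missing)) {
    stop_cyp("unlabeled leaves: ", paste(missing, collapse = ", "),
             class = "cyp_input_error")
  }
  fam <- families[tips]
  groups <- split(tips, fam)
  multi <- groups[lengths(groups) >= 2L]
  if (length(multi) == 0L) return(NA_real_)
  # every edge split, as the tip set on the descendant side
  parts <- ape::prop.part(tree)
  sides <- lapply(parts, function(idx) tips[idx])
  is_mono <- function(members) {
    if (length(members) == length(tips)) return(TRUE)
    for (s in sides) {
      if (setequal(s, members) || setequal(setdiff(tips, s), members)) {
        return(TRUE)
      }
    }
    FALSE
  }
  mean(vapply(multi, is_mono, TRUE))
}
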