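#' Build a species-by-family census table
#'
#' Aggregates classifier assignments into an integer count matrix with one
#' row per species and one column per family token, columns ordered by
#' descending total count then name. A parallel subfamily-level matrix is
#' included when the assignments carry subfamilies.
#'
#' @param assignments data frame with columns `species_id`, `family` and
#'   optionally `subfamily` (as produced by [classify_proteome()]).
#' @return a `census_table`: list with `family` (species x family integer
#'   matrix) and `subfamily` (species x subfamily matrix or `NULL`).
#' @export
build_census <- function(assignments) {
  stopifnot(is.data.frame(assignments),
            all(c("species_id", "family") %in% names(assignments)))
  count_matrix <- function(col) {
    if (nrow(assignments) == 0L) {
      return(matrix(0L, 0, 0))
    }
    tab <- table(assignments$species_id, assignments[[col]])
    m <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                dimnames = dimnames(tab))
    ord <- order(-colSums(m), colnames(m))
    m[, ord, drop = FALSE]
  }
  fam <- count_matrix("family")
  subfam <- if ("subfamily" %in% names(assignments)) count_matrix("subfamily")
  structure(list(family = fam, subfamily = subfam), class = "census_table")
}

#' @export
print.census_table <- function(x, ...) {
  cat("<census_table> ", nrow(x$family), " species x ",
      ncol(x$family), " families",
      if (!is.null(x$subfamily)) paste0(" (", ncol(x$subfamily), " subfamilies)"),
      "\n", sep = "")
  invisible(x)
}

#' Top families by total count ("blooming")
#'
#' A bloomed family is one with many members across the population. This
#' ranks families by total census count (ties broken by name) and returns
#' the top `k` — a descriptive ranking, not a statistical test.
#'
#' @param census a [build_census()] result.
#' @param k number of families to return (default all).
#' @return data frame `family`, `count`, best first.
#' @export
dominant_families <- function(census, k = Inf) {
  stopifnot(inherits(census, "census_table"))
  totals <- colSums(census$family)
  ord <- order(-totals, names(totals))
  n <- min(k, length(totals))
  data.frame(family = names(totals)[ord][seq_len(n)],
             count = as.integer(totals[ord][seq_len(n)]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Families present in every species
#'
#' @param census a [build_census()] result.
#' @return character vector of family tokens with a nonzero count in every
#'   species row (empty when none is conserved).
#' @export
conserved_families <- function(census) {
  stopifnot(inherits(census, "census_table"))
  if (ncol(census$family) == 0L) return(character(0))
  colnames(census$family)[colSums(census$family > 0) == nrow(census$family)]
}

#' P450 diversity percentage
#'
#' `100 * F / (P * S)` where `F` is the number of P450 families, `P` the
#' total number of P450s, and `S` the number of species analyzed. Dividing
#' by both the P450 total and the species count nullifies population size,
#' making the percentage comparable across taxa sampled at different
#' depths. Reported half-up rounded to 2 decimals.
#'
#' @param n_families `F`.
#' @param n_p450s `P` (> 0).
#' @param n_species `S` (> 0).
#' @return percentage, rounded to 2 decimals.
#' @examples
#' p450_diversity_percentage(36, 341, 114)  # 0.09
#' @export
p450_diversity_percentage <- function(n_families, n_p450s, n_species) {
  if (n_p450s <= 0 || n_species <= 0) {
    stop_cyp("P450 and species counts must be positive",
             class = "cyp_domain_error")
  }
  round_half_up(100 * n_families / (n_p450s * n_species), 2)
}

#' Gene-cluster diversity percentage
#'
#' `100 * T / (C * S)` where `T` is the number of distinct BGC types, `C`
#' the total number of BGCs, and `S` the number of species analyzed — the
#' same normalization as [p450_diversity_percentage()] applied to
#' secondary-metabolite cluster types. Reported half-up rounded to 2
#' decimals.
#'
#' @param n_types `T`.
#' @param n_clusters `C` (> 0).
#' @param n_species `S` (> 0).
#' @return percentage, rounded to 2 decimals.
#' @examples
#' gene_cluster_diversity_percentage(73, 770, 114)  # 0.08
#' @export
gene_cluster_diversity_percentage <- function(n_types, n_clusters, n_species) {
  if (n_clusters <= 0 || n_species <= 0) {
    stop_cyp("cluster and species counts must be positive",
             class = "cyp_domain_error")
  }
  round_half_up(100 * n_types / (n_clusters * n_species), 2)
}

#' Per-species averages and BGC membership share
#'
#' Average P450s per species, average BGCs per species, and the percentage
#' of P450s located inside BGCs, each rounded half-up to the nearest
#' integer (the convention of the comparative summary tables).
#'
#' @param n_p450s total P450s `P`.
#' @param n_species species analyzed `S` (> 0).
#' @param n_clusters total BGCs `C`.
#' @param n_in_bgc P450s inside BGCs (must not exceed `P`).
#' @return named numeric vector `avg_p450`, `avg_bgc`, `pct_in_bgc`.
#' @examples
#' averages_and_shares(341, 114, 770, 27)  # 3, 7, 8
#' @export
averages_and_shares <- function(n_p450s, n_species, n_clusters, n_in_bgc) {
  if (n_species <= 0) {
    stop_cyp("species count must be positive", class = "cyp_domain_error")
  }
  if (n_in_bgc > n_p450s) {
    stop_cyp("P450s inside BGCs (", n_in_bgc, ") exceed total P450s (",
             n_p450s, ")", class = "cyp_domain_error")
  }
  c(avg_p450 = round_half_up(n_p450s / n_species),
    avg_bgc = round_half_up(n_clusters / n_species),
    pct_in_bgc = if (n_p450s > 0) round_half_up(100 * n_in_bgc / n_p450s) else 0)
}

#' Diversity summary for one taxon
#'
#' Bundles the raw counts of a taxon's census with every derived statistic
#' of the comparative summary table.
#'
#' @param taxon taxon name.
#' @param n_species species analyzed `S`.
#' @param n_p450s total P450s `P`.
#' @param n_families P450 families `F`.
#' @param n_subfamilies P450 subfamilies `SF`.
#' @param n_clusters total BGCs `C`.
#' @param n_types distinct BGC types `T`.
#' @param n_in_bgc P450s inside BGCs.
#' @param dominant_family dominant family token (optional).
#' @return a `diversity_summary` list with the counts plus `avg_p450`,
#'   `avg_bgc`, `p450_div_pct`, `cluster_div_pct`, `pct_in_bgc`.
#' @export
diversity_summary <- function(taxon, n_species, n_p450s, n_families,
                              n_subfamilies, n_clusters, n_types, n_in_bgc,
                              dominant_family = NA_character_) {
  avg <- averages_and_shares(n_p450s, n_species, n_clusters, n_in_bgc)
  structure(list(
    taxon = taxon,
    n_species = n_species, n_p450s = n_p450s, n_families = n_families,
    n_subfamilies = n_subfamilies, n_clusters = n_clusters,
    n_types = n_types, n_in_bgc = n_in_bgc,
    dominant_family = dominant_family,
    avg_p450 = unname(avg["avg_p450"]),
    avg_bgc = unname(avg["avg_bgc"]),
    p450_div_pct = p450_diversity_percentage(n_families, n_p450s, n_species),
    cluster_div_pct = gene_cluster_diversity_percentage(n_types, n_clusters,
                                                        n_species),
    pct_in_bgc = unname(avg["pct_in_bgc"])),
    class = "diversity_summary")
}

#' Comparative summary table across taxa
#'
#' One column per taxon, one row per count or derived statistic — the
#' machine-readable analogue of a cross-taxon "key features" table. Every
#' derived row is recomputed from the count rows via the formulas in
#' [p450_diversity_percentage()], [gene_cluster_diversity_percentage()] and
#' [averages_and_shares()].
#'
#' @param summaries list of [diversity_summary()] objects.
#' @return data frame with a `feature` column and one column per taxon.
#' @export
summary_table <- function(summaries) {
  stopifnot(length(summaries) >= 1,
            all(vapply(summaries, inherits, TRUE, "diversity_summary")))
  features <- c("n_species", "n_p450s", "n_families", "n_subfamilies",
                "dominant_family", "n_clusters", "n_types", "n_in_bgc",
                "avg_p450", "p450_div_pct", "avg_bgc", "cluster_div_pct",
                "pct_in_bgc")
  out <- data.frame(feature = features, stringsAsFactors = FALSE)
  for (s in summaries) {
    out[[s$taxon]] <- vapply(features,
                             function(f) as.character(s[[f]]), "")
  }
  out
}
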