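#' Published comparative census counts
#'
#' Packaged count rows from a published comparative census of cytochrome
#' P450s and secondary-metabolite BGCs in four bacterial taxa
#' (Cyanobacteria, and Bacillus, mycobacterial and Streptomyces species):
#' species analyzed, total P450s, families, subfamilies, dominant family,
#' total BGCs, distinct BGC types, and P450s located inside BGCs. These
#' are inputs for the derived statistics — every average and diversity
#' percentage is recomputed from them, never stored.
#'
#' @return data frame, one row per taxon.
#' @export
load_comparative_counts <- function() {
  path <- system.file("extdata", "comparative_counts.tsv",
                      package = "cypcensus", mustWork = TRUE)
  df <- read_tsv_file(path)
  int_cols <- setdiff(names(df), c("taxon", "dominant_family"))
  df[int_cols] <- lapply(df[int_cols], as.integer)
  df
}

#' Published inventory of cyanobacterial P450s inside BGCs
#'
#' Packaged worked example: the 27 cyanobacterial P450s reported inside
#' secondary-metabolite biosynthetic gene clusters, with the detected
#' cluster type string, the most similar known cluster, and its percent
#' similarity (blank where no known cluster matched). Cluster type strings
#' are kept verbatim — hybrid clusters such as `"NRPS, T1PKS"` count as
#' their own type. A few P450s occur in two clusters and therefore appear
#' twice; counts are per row.
#'
#' @return data frame with columns `p450_name`, `cluster_type`,
#'   `most_similar_known_cluster`, `similarity_percent`.
#' @export
load_bgc_p450_inventory <- function() {
  path <- system.file("extdata", "cyano_bgc_p450s.tsv",
                      package = "cypcensus", mustWork = TRUE)
  df <- read_tsv_file(path)
  df$similarity_percent <- suppressWarnings(as.numeric(df$similarity_percent))
  df
}

#' Summaries of the packaged comparative counts
#'
#' Convenience wrapper: one [diversity_summary()] per taxon of
#' [load_comparative_counts()].
#'
#' @return named list of `diversity_summary` objects.
#' @export
comparative_summaries <- function() {
  counts <- load_comparative_counts()
  out <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    diversity_summary(r$taxon, r$n_species, r$n_p450s, r$n_families,
                      r$n_subfamilies, r$n_clusters, r$n_types, r$n_in_bgc,
                      r$dominant_family)
  })
  names(out) <- counts$taxon
  out
}
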