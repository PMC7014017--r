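#' Load a table of gene loci
#'
#' Gene coordinates use the GenBank/GFF3 convention throughout: 1-based,
#' start and end inclusive. Accepted inputs are a TSV with columns
#' `protein_id`, `species_id`, `contig`, `start`, `end`, `strand`, or a
#' GFF3 file (CDS/gene features; the `ID` attribute is the protein id and
#' `species_id` must then be supplied).
#'
#' @param path TSV or GFF3 (`.gff`/`.gff3`) file.
#' @param species_id species identifier, required for GFF3 input.
#' @return data frame of validated loci.
#' @export
load_gene_loci <- function(path, species_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) {
    if (is.null(species_id)) {
      stop_cyp("species_id is required when loading loci from GFF3",
               class = "cyp_input_error")
    }
    gr <- rtracklayer_import_gff(path)
    df <- data.frame(protein_id = gr$ID,
                     species_id = species_id,
                     contig = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr),
                     strand = as.character(GenomicRanges::strand(gr)),
                     stringsAsFactors = FALSE)
  } else {
    df <- read_tsv_file(path)
    need <- c("protein_id", "species_id", "contig", "start", "end", "strand")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop_cyp("loci table ", path, " lacks columns: ",
               paste(miss, collapse = ", "), class = "cyp_parse_error")
    }
    df$start <- as.integer(df$start)
    df$end <- as.integer(df$end)
  }
  validate_loci(df, path)
}

#' @noRd
rtracklayer_import_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type %in% c("gene", "CDS")]
  if (is.null(gr$ID) || anyNA(gr$ID)) {
    stop_cyp("GFF3 features in ", path, " lack ID attributes",
             class = "cyp_parse_error")
  }
  gr
}

#' @noRd
validate_loci <- function(df, path) {
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 1 |
                 df$start > df$end)
  if (length(bad)) {
    stop_cyp("invalid coordinates in ", path, " at data line ",
             bad[1], " (protein ", df$protein_id[bad[1]],
             "): need 1 <= start <= end", class = "cyp_parse_error")
  }
  if (!all(df$strand %in% c("+", "-"))) {
    bad <- which(!(df$strand %in% c("+", "-")))[1]
    stop_cyp("unknown strand '", df$strand[bad], "' in ", path,
             " at data line ", bad, class = "cyp_parse_error")
  }
  key <- paste(df$species_id, df$protein_id)
  if (anyDuplicated(key)) {
    stop_cyp("duplicate protein id in ", path, ": ",
             key[duplicated(key)][1], class = "cyp_parse_error")
  }
  df
}

#' Load a table of secondary-metabolite BGCs
#'
#' A documented dialect mirroring cluster-detection summary output: one
#' row per cluster with `cluster_id`, `species_id`, `contig`, `start`,
#' `end` (1-based inclusive), `cluster_type` (component tokens joined by
#' `", "` in detector order, e.g. `"NRPS, T1PKS"`), and optionally
#' `most_similar_known_cluster` and `similarity_percent`. TSV, or JSON
#' (an array of objects with the same keys) when the file ends `.json`.
#'
#' @param path TSV or JSON file.
#' @return data frame of validated clusters.
#' @export
load_bgc_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  df <- if (ext == "json") {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    read_tsv_file(path)
  }
  need <- c("cluster_id", "species_id", "contig", "start", "end",
            "cluster_type")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_cyp("cluster table ", path, " lacks columns: ",
             paste(miss, collapse = ", "), class = "cyp_parse_error")
  }
  if (!"most_similar_known_cluster" %in% names(df)) {
    df$most_similar_known_cluster <- ""
  }
  if (!"similarity_percent" %in% names(df)) {
    df$similarity_percent <- NA_real_
  }
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$similarity_percent <- suppressWarnings(as.numeric(df$similarity_percent))
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 1 |
                 df$start > df$end)
  if (length(bad)) {
    stop_cyp("invalid coordinates in ", path, " at data line ", bad[1],
             " (cluster ", df$cluster_id[bad[1]], "): need 1 <= start <= end",
             class = "cyp_parse_error")
  }
  if (anyDuplicated(df$cluster_id)) {
    stop_cyp("duplicate cluster_id in ", path, ": ",
             df$cluster_id[duplicated(df$cluster_id)][1],
             class = "cyp_parse_error")
  }
  if (any(!nzchar(df$cluster_type))) {
    stop_cyp("empty cluster_type in ", path, " at data line ",
             which(!nzchar(df$cluster_type))[1], class = "cyp_parse_error")
  }
  df
}

#' Convert 0-based half-open coordinates to 1-based inclusive
#'
#' For loci or cluster tables exported from BED-style tooling.
#'
#' @param df data frame with `start` and `end` columns in 0-based
#'   half-open convention.
#' @return the data frame with coordinates shifted to 1-based inclusive.
#' @export
from_zero_based <- function(df) {
  df$start <- as.integer(df$start) + 1L
  df$end <- as.integer(df$end)
  df
}

#' Intersect P450 gene loci with BGC intervals
#'
#' A P450 belongs to a cluster when its gene interval overlaps the cluster
#' interval on the same species and contig. The default rule counts any
#' overlap of at least one base (strand ignored); `rule = "contained"`
#' requires the gene to lie entirely inside the cluster. Each
#' (protein, cluster) pair is reported at most once.
#'
#' @param loci data frame from [load_gene_loci()].
#' @param clusters data frame from [load_bgc_table()].
#' @param assignments optional classifier assignments (`protein_id`,
#'   `family`) used to attach the P450 family to each membership.
#' @param rule `"any_overlap"` (default) or `"contained"`.
#' @return data frame with `protein_id`, `cluster_id`, `p450_family`,
#'   `overlap_bases`.
#' @export
p450s_in_clusters <- function(loci, clusters, assignments = NULL,
                              rule = c("any_overlap", "contained")) {
  rule <- match.arg(rule)
  empty <- data.frame(protein_id = character(0), cluster_id = character(0),
                      p450_family = character(0), overlap_bases = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(loci) == 0L || nrow(clusters) == 0L) return(empty)
  space <- function(df) paste0(df$species_id, "\r", df$contig)
  gl <- GenomicRanges::GRanges(space(loci),
                               IRanges::IRanges(loci$start, loci$end))
  gc <- GenomicRanges::GRanges(space(clusters),
                               IRanges::IRanges(clusters$start, clusters$end))
  # union the seqlevels so disjoint namespaces do not error
  lv <- union(as.character(S4Vectors::runValue(GenomicRanges::seqnames(gl))),
              as.character(S4Vectors::runValue(GenomicRanges::seqnames(gc))))
  GenomeInfoDb::seqlevels(gl) <- lv
  GenomeInfoDb::seqlevels(gc) <- lv
  hits <- GenomicRanges::findOverlaps(
    gl, gc, type = if (rule == "contained") "within" else "any",
    minoverlap = 1L)
  if (length(hits) == 0L) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(gl[qi], gc[si]))
  out <- data.frame(protein_id = loci$protein_id[qi],
                    cluster_id = clusters$cluster_id[si],
                    p450_family = NA_character_,
                    overlap_bases = as.integer(ov),
                    stringsAsFactors = FALSE)
  if (!is.null(assignments)) {
    out$p450_family <- assignments$family[
      match(out$protein_id, assignments$protein_id)]
  }
  out <- out[!duplicated(paste(out$protein_id, out$cluster_id)), , drop = FALSE]
  out[order(out$protein_id, out$cluster_id), , drop = FALSE]
}

#' Tally clusters per canonical type string
#'
#' Hybrid combinations (e.g. `"NRPS, T1PKS"`) count as their own type;
#' the tally key is the verbatim component-ordered type string.
#'
#' @param clusters data frame with a `cluster_type` column.
#' @return data frame `cluster_type`, `count`, descending count then name.
#' @export
tally_cluster_types <- function(clusters) {
  if (nrow(clusters) == 0L) {
    return(data.frame(cluster_type = character(0), count = integer(0)))
  }
  tab <- table(clusters$cluster_type)
  out <- data.frame(cluster_type = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$cluster_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-family breakdown of BGC-resident P450s
#'
#' Counts memberships per P450 family with integer-rounded percentage
#' shares, ranked descending.
#'
#' @param memberships data frame with a `p450_family` column (one row per
#'   membership).
#' @return data frame `family`, `count`, `share_percent`.
#' @export
bgc_family_breakdown <- function(memberships) {
  if (nrow(memberships) == 0L) {
    return(data.frame(family = character(0), count = integer(0),
                      share_percent = numeric(0)))
  }
  tab <- table(memberships$p450_family)
  total <- sum(tab)
  out <- data.frame(family = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$share_percent <- round_half_up(100 * out$count / total)
  out <- out[order(-out$count, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Membership report with cluster type and known-cluster similarity
#'
#' One row per membership: the P450 label, the verbatim cluster type
#' string, the most similar known cluster and its similarity percent
#' (blank where the cluster matched no known cluster).
#'
#' @param clusters data frame from [load_bgc_table()].
#' @param memberships data frame from [p450s_in_clusters()]; an optional
#'   `p450_name` column overrides `protein_id` as the displayed label.
#' @return data frame with columns `p450_name`, `cluster_type`,
#'   `most_similar_known_cluster`, `similarity_percent`.
#' @export
similarity_report <- function(clusters, memberships) {
  unknown <- setdiff(memberships$cluster_id, clusters$cluster_id)
  if (length(unknown)) {
    stop_cyp("memberships reference unknown clusters: ",
             paste(unknown, collapse = ", "), class = "cyp_input_error")
  }
  idx <- match(memberships$cluster_id, clusters$cluster_id)
  label <- if ("p450_name" %in% names(memberships)) {
    memberships$p450_name
  } else {
    memberships$protein_id
  }
  data.frame(
    p450_name = label,
    cluster_type = clusters$cluster_type[idx],
    most_similar_known_cluster = clusters$most_similar_known_cluster[idx],
    similarity_percent = clusters$similarity_percent[idx],
    stringsAsFactors = FALSE)
}
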