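#' Pipeline run configuration
#'
#' One flat, validated configuration drives a whole census run; a
#' serialized copy is written into the output directory so a run is fully
#' reproducible from its artifacts. All randomness flows from the single
#' `seed`. Unknown fields are rejected.
#'
#' @param out_dir output directory.
#' @param seed integer seed (< 2^31).
#' @param thresholds a [cyp_thresholds()].
#' @param scheme a [scoring_scheme()].
#' @param triage a [triage_params()].
#' @param overlap_rule BGC membership rule, `"any_overlap"` or
#'   `"contained"`.
#' @param linkage heat-map clustering linkage.
#' @param build_tree also build the all-vs-all identity distance matrix
#'   and NJ tree (the quadratic-cost stage; default `TRUE`).
#' @param ... rejected; present so typos fail loudly.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L,
                       thresholds = cyp_thresholds(),
                       scheme = scoring_scheme(),
                       triage = triage_params(),
                       overlap_rule = c("any_overlap", "contained"),
                       linkage = c("average", "single", "complete"),
                       build_tree = TRUE,
                       ...) {
  extra <- list(...)
  if (length(extra)) {
    stop_cyp("unknown config fields: ",
             paste(names(extra), collapse = ", "),
             class = "cyp_config_error")
  }
  stopifnot(is.numeric(seed), seed == as.integer(seed))
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 thresholds = thresholds, scheme = scheme,
                 triage = triage,
                 overlap_rule = match.arg(overlap_rule),
                 linkage = match.arg(linkage),
                 build_tree = isTRUE(build_tree)),
            class = "run_config")
}

#' @noRd
serialize_config <- function(config, path) {
  cfg <- list(version = 1L,
              seed = config$seed,
              family_threshold = config$thresholds$family,
              subfamily_threshold = config$thresholds$subfamily,
              inclusive_thresholds = config$thresholds$inclusive,
              substitution_matrix = config$scheme$matrix_name,
              gap_open = config$scheme$gap_open,
              gap_extend = config$scheme$gap_extend,
              identity_denominator = config$scheme$identity_denominator,
              min_full_length = config$triage$min_full_length,
              heme_pattern = config$triage$heme_pattern,
              require_exxr = config$triage$require_exxr,
              overlap_rule = config$overlap_rule,
              linkage = config$linkage,
              build_tree = config$build_tree)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full census pipeline on a synthetic study
#'
#' Stages: simulate (generate a ground-truthed bundle), triage, classify,
#' census + presence/absence profile clustering, distance tree, BGC
#' cross-referencing, and the diversity-statistics summary. Every stage
#' writes deterministic TSV/Newick/JSON artifacts under `config$out_dir`;
#' identical config + seed produce byte-identical trees.
#'
#' @param config a [run_config()].
#' @param bundle optionally, a pre-built [default_truth_bundle()]; when
#'   omitted one is generated from `config$seed`.
#' @return invisible list with all in-memory stage results (`bundle`,
#'   `triage`, `classification`, `census`, `profile`, `tree`,
#'   `memberships`, `summary`, `stage_counts`).
#' @export
run_pipeline <- function(config, bundle = NULL) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  serialize_config(config, file.path(out, "config.json"))

  # simulate
  if (is.null(bundle)) {
    bundle <- default_truth_bundle(seed = config$seed,
                                   scheme = config$scheme)
  }
  write_truth_bundle(bundle, file.path(out, "simulated"))

  # triage
  tri <- triage_proteome(bundle$proteome$records, config$triage)
  write_tsv_file(tri$records[, c("protein_id", "species_id", "category",
                                 "reasons")],
                 file.path(out, "triage.tsv"))

  # classify
  cls <- classify_proteome(tri$full_length, bundle$refdb,
                           config$thresholds, config$scheme)
  write_tsv_file(cls$assignments, file.path(out, "assignments.tsv"))

  # census + profiles
  census <- build_census(cls$assignments)
  fam_df <- data.frame(species_id = rownames(census$family),
                       census$family, check.names = FALSE,
                       stringsAsFactors = FALSE)
  write_tsv_file(fam_df, file.path(out, "census_family.tsv"))
  presence <- encode_presence(census)
  orders <- hierarchical_cluster(presence, linkage = config$linkage)
  export_heatmap(presence, orders, file.path(out, "heatmap.tsv"))
  writeLines(c(orders$rows$newick, orders$cols$newick),
             file.path(out, "heatmap_dendrograms.nwk"))

  # distance tree over classified P450s
  seqs <- setNames(tri$full_length$sequence, tri$full_length$protein_id)
  tree <- NULL
  if (config$build_tree && length(seqs) >= 3L) {
    d <- distance_matrix(seqs, config$scheme)
    write_phylip_distances(d, file.path(out, "distances.phy"))
    tree <- nj_tree(d)
    write_newick(tree, file.path(out, "p450_nj.nwk"))
  }

  # BGC cross-referencing
  memb <- p450s_in_clusters(bundle$annotation$loci,
                            bundle$annotation$clusters,
                            cls$assignments, rule = config$overlap_rule)
  write_tsv_file(memb, file.path(out, "memberships.tsv"))
  write_tsv_file(similarity_report(bundle$annotation$clusters, memb),
                 file.path(out, "bgc_p450_report.tsv"))
  write_tsv_file(tally_cluster_types(bundle$annotation$clusters),
                 file.path(out, "cluster_type_tally.tsv"))
  write_tsv_file(bgc_family_breakdown(memb),
                 file.path(out, "bgc_family_breakdown.tsv"))

  # diversity statistics
  summ <- diversity_summary(
    taxon = "synthetic",
    n_species = length(unique(bundle$proteome$records$species_id)),
    n_p450s = nrow(cls$assignments),
    n_families = ncol(census$family),
    n_subfamilies = if (!is.null(census$subfamily)) ncol(census$subfamily) else 0L,
    n_clusters = nrow(bundle$annotation$clusters),
    n_types = nrow(tally_cluster_types(bundle$annotation$clusters)),
    n_in_bgc = length(unique(memb$protein_id)),
    dominant_family = dominant_families(census, 1)$family[1])
  jsonlite::write_json(unclass(summ), file.path(out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  counts <- c(candidates_in = nrow(bundle$proteome$records),
              full_length = unname(tri$counts["full_length"]),
              families = ncol(census$family),
              clusters = nrow(bundle$annotation$clusters),
              memberships = nrow(memb))
  writeLines(paste(names(counts), counts, sep = "\t"),
             file.path(out, "stage_counts.tsv"))

  invisible(list(bundle = bundle, triage = tri, classification = cls,
                 census = census, profile = orders, tree = tree,
                 memberships = memb, summary = summ,
                 stage_counts = counts))
}

#' Write a distance matrix in square PHYLIP format
#' @param d symmetric labeled distance matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phylip_distances <- function(d, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  lines <- c(sprintf("%5d", nrow(d)),
             vapply(seq_len(nrow(d)), function(i) {
               paste(c(sprintf("%-10s", rownames(d)[i]),
                       sprintf("%.6f", d[i, ])), collapse = " ")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
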