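# Synthetic ground-truthed inputs.
#
# Every generator takes an explicit seed and is fully deterministic given
# it (set.seed is called internally). Planted P450s carry the P450
# heme-binding motif and an E-x-x-R motif at generation time; both windows
# are protected from mutation so triage categories hold by construction.

HEME_MOTIF <- "FGAGRHRCIG"
EXXR_MOTIF <- "EGLR"

#' @noRd
random_aa_seq <- function(len) {
  paste(sample(AA_STANDARD, len, replace = TRUE), collapse = "")
}

# random backbone with both P450 motifs embedded at fixed offsets
#' @noRd
p450_like_seq <- function(len) {
  stopifnot(len >= 120)
  s <- random_aa_seq(len)
  exxr_at <- max(1L, len - 110L)
  heme_at <- len - 59L
  substr(s, exxr_at, exxr_at + nchar(EXXR_MOTIF) - 1L) <- EXXR_MOTIF
  substr(s, heme_at, heme_at + nchar(HEME_MOTIF) - 1L) <- HEME_MOTIF
  s
}

#' @noRd
motif_positions <- function(seq) {
  out <- integer(0)
  for (pat in c(HEME_MOTIF, EXXR_MOTIF)) {
    at <- regexpr(pat, seq, fixed = TRUE)
    if (at > 0) out <- c(out, seq(at, at + nchar(pat) - 1L))
  }
  out
}

#' Mutate a sequence to a target percent identity
#'
#' Applies random substitutions (uniform over the 19 non-identical
#' standard residues; no indels) and iteratively adjusts the number of
#' substituted positions until the measured global-alignment identity to
#' the input is within `tolerance` points of `target_percent`. The
#' contract is checked by measurement, not assumed from the substitution
#' count, because heavily mutated pairs can align with gaps.
#'
#' @param seq amino-acid sequence.
#' @param target_percent target identity, 10–100.
#' @param seed integer seed.
#' @param scheme a [scoring_scheme()] used for the measurement.
#' @param protect integer positions never substituted (e.g. motif
#'   windows).
#' @param tolerance acceptable deviation in identity points (default 2).
#' @param max_iter iteration cap before giving up.
#' @return the mutated sequence, with attribute `measured_identity`.
#' @export
mutate_to_identity <- function(seq, target_percent, seed,
                               scheme = scoring_scheme(),
                               protect = integer(0),
                               tolerance = 2, max_iter = 40) {
  stopifnot(target_percent >= 10, target_percent <= 100)
  if (target_percent == 100) {
    return(structure(seq, measured_identity = 100))
  }
  set.seed(seed)
  L <- nchar(seq)
  free <- setdiff(seq_len(L), protect)
  k <- min(length(free), max(1L, round(L * (1 - target_percent / 100))))
  for (iter in seq_len(max_iter)) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    pos <- sample(free, k)
    for (p in pos) {
      chars[p] <- sample(setdiff(AA_STANDARD, chars[p]), 1L)
    }
    mut <- paste(chars, collapse = "")
    got <- global_align(seq, mut, scheme)$identity_percent
    if (abs(got - target_percent) <= tolerance) {
      return(structure(mut, measured_identity = got))
    }
    # shift the substitution budget by the measured error
    k <- k + round(L * (got - target_percent) / 100)
    k <- min(length(free), max(1L, k))
  }
  stop_cyp("could not reach ", target_percent, "% identity within ",
           max_iter, " iterations", class = "cyp_generation_error")
}

#' Generate a reference database of named synthetic P450s
#'
#' Families are founded by independent random sequences, rejection-sampled
#' so all inter-family identities stay below `max_family_identity`.
#' Subfamily exemplars are mutated copies of their family founder at
#' 60–90% identity. Family numbers start at 501; subfamilies are lettered
#' A, B, ... with protein number 1.
#'
#' @param n_families number of families (>= 1).
#' @param subfamilies_per_family subfamily exemplars per family (>= 1).
#' @param seq_length reference length in residues (default 400).
#' @param seed integer seed.
#' @param scheme a [scoring_scheme()].
#' @param max_family_identity inter-family identity ceiling (default 30).
#' @return a [reference_db()].
#' @export
make_reference_db <- function(n_families, subfamilies_per_family = 1L,
                              seq_length = 400L, seed = 1L,
                              scheme = scoring_scheme(),
                              max_family_identity = 30) {
  stopifnot(n_families >= 1, subfamilies_per_family >= 1)
  set.seed(seed)
  founders <- character(0)
  for (i in seq_len(n_families)) {
    ok <- FALSE
    for (try in 1:25) {
      cand <- p450_like_seq(seq_length)
      ids <- vapply(founders, function(f)
        global_align(cand, f, scheme)$identity_percent, 0)
      if (all(ids < max_family_identity)) { ok <- TRUE; break }
    }
    if (!ok) {
      stop_cyp("could not sample family founder ", i, " below ",
               max_family_identity, "% inter-family identity",
               class = "cyp_generation_error")
    }
    founders[i] <- cand
  }
  sub_seeds <- sample.int(.Machine$integer.max %/% 2,
                          n_families * subfamilies_per_family)
  names_out <- character(0)
  seqs_out <- character(0)
  targets <- if (subfamilies_per_family > 1L) {
    seq(88, 62, length.out = subfamilies_per_family - 1L)
  } else numeric(0)
  idx <- 0L
  for (i in seq_len(n_families)) {
    fam_no <- 500L + i
    for (j in seq_len(subfamilies_per_family)) {
      idx <- idx + 1L
      nm <- paste0("CYP", fam_no, LETTERS[j], 1)
      sq <- if (j == 1L) {
        founders[i]
      } else {
        as.character(mutate_to_identity(
          founders[i], targets[j - 1L], seed = sub_seeds[idx],
          scheme = scheme, protect = motif_positions(founders[i])))
      }
      names_out <- c(names_out, nm)
      seqs_out <- c(seqs_out, sq)
    }
  }
  reference_db(names_out, seqs_out)
}

#' Per-species composition of a synthetic proteome
#'
#' @param species_id species identifier.
#' @param planted_refs reference names the planted P450s derive from.
#' @param planted_identities target identity (one per planted P450).
#' @param n_decoys non-P450 decoy proteins (no heme motif).
#' @param n_fragments truncated motif-bearing fragments.
#' @return a `species_spec` list.
#' @export
species_spec <- function(species_id, planted_refs = character(0),
                         planted_identities = numeric(0),
                         n_decoys = 0L, n_fragments = 0L) {
  stopifnot(length(planted_refs) == length(planted_identities))
  structure(list(species_id = species_id,
                 planted_refs = planted_refs,
                 planted_identities = planted_identities,
                 n_decoys = as.integer(n_decoys),
                 n_fragments = as.integer(n_fragments)),
            class = "species_spec")
}

#' Generate a synthetic proteome with known ground truth
#'
#' For each species: planted P450s are references mutated to their target
#' identity (motif windows protected, so they triage full length); decoys
#' are random proteins rejection-sampled to lack the heme motif (false
#' positives); fragments are motif-bearing windows shorter than the
#' full-length threshold. The truth table records the planted category,
#' source reference, and its family/subfamily for every protein.
#'
#' @param specs list of [species_spec()] objects.
#' @param refdb a [reference_db()].
#' @param seed integer seed.
#' @param scheme a [scoring_scheme()].
#' @return list with `records` (protein_id, species_id, sequence) and
#'   `truth` (protein_id, species_id, category, ref_name, target_identity,
#'   true_family, true_subfamily).
#' @export
make_proteome <- function(specs, refdb, seed = 1L,
                          scheme = scoring_scheme()) {
  stopifnot(all(vapply(specs, inherits, TRUE, "species_spec")),
            inherits(refdb, "reference_db"))
  set.seed(seed)
  recs <- list()
  truth <- list()
  add <- function(pid, sid, sq, category, ref = NA_character_,
                  target = NA_real_) {
    recs[[length(recs) + 1L]] <<- data.frame(
      protein_id = pid, species_id = sid, sequence = sq,
      stringsAsFactors = FALSE)
    fam <- subfam <- NA_character_
    if (!is.na(ref)) {
      nm <- parse_p450_name(ref)
      fam <- family_token(nm)
      subfam <- subfamily_token(nm)
    }
    truth[[length(truth) + 1L]] <<- data.frame(
      protein_id = pid, species_id = sid, category = category,
      ref_name = ref, target_identity = target,
      true_family = fam, true_subfamily = subfam,
      stringsAsFactors = FALSE)
  }
  for (sp in specs) {
    n_total <- length(sp$planted_refs) + sp$n_decoys + sp$n_fragments
    item_seeds <- sample.int(.Machine$integer.max %/% 2, max(n_total, 1L))
    counter <- 0L
    for (i in seq_along(sp$planted_refs)) {
      counter <- counter + 1L
      ref_row <- match(sp$planted_refs[i], refdb$entries$name)
      if (is.na(ref_row)) {
        stop_cyp("species spec references unknown reference: ",
                 sp$planted_refs[i], class = "cyp_input_error")
      }
      ref_seq <- refdb$entries$sequence[ref_row]
      sq <- as.character(mutate_to_identity(
        ref_seq, sp$planted_identities[i], seed = item_seeds[counter],
        scheme = scheme, protect = motif_positions(ref_seq)))
      add(sprintf("%s_p%03d", sp$species_id, counter), sp$species_id, sq,
          "full_length", sp$planted_refs[i], sp$planted_identities[i])
    }
    for (i in seq_len(sp$n_fragments)) {
      counter <- counter + 1L
      set.seed(item_seeds[counter])
      frag_full <- p450_like_seq(400L)
      heme_at <- regexpr(HEME_MOTIF, frag_full, fixed = TRUE)
      lo <- max(1L, heme_at - 120L)
      sq <- substr(frag_full, lo, min(nchar(frag_full), lo + 149L))
      add(sprintf("%s_p%03d", sp$species_id, counter), sp$species_id, sq,
          "fragment")
    }
    for (i in seq_len(sp$n_decoys)) {
      counter <- counter + 1L
      set.seed(item_seeds[counter])
      repeat {
        sq <- random_aa_seq(350L)
        if (!grepl("F..G...C.G", sq)) break
      }
      add(sprintf("%s_p%03d", sp$species_id, counter), sp$species_id, sq,
          "false_positive")
    }
  }
  if (length(recs) == 0L) {
    return(list(records = data.frame(protein_id = character(0),
                                     species_id = character(0),
                                     sequence = character(0)),
                truth = data.frame(protein_id = character(0),
                                   species_id = character(0),
                                   category = character(0),
                                   ref_name = character(0),
                                   target_identity = numeric(0),
                                   true_family = character(0),
                                   true_subfamily = character(0))))
  }
  list(records = do.call(rbind, c(recs, list(make.row.names = FALSE))),
       truth = do.call(rbind, c(truth, list(make.row.names = FALSE))))
}

#' Generate gene loci and a BGC table consistent with a proteome
#'
#' Genes are laid head-to-tail (with intergenic spacers) on one synthetic
#' contig per species, ordered so that each cluster's member genes are
#' adjacent; each cluster interval is drawn 50 bp beyond its outermost
#' member genes. With spacers wider than that margin, interval
#' intersection recovers exactly the specified membership.
#'
#' @param proteome result of [make_proteome()].
#' @param cluster_spec data frame with columns `cluster_id`, `species_id`,
#'   `cluster_type`, `members` (protein ids joined by `";"`), and
#'   optionally `most_similar_known_cluster`, `similarity_percent`.
#' @param contig_length synthetic contig size cap per species (default
#'   2e6 bases).
#' @return list with `loci` and `clusters` data frames (1-based inclusive
#'   coordinates) plus `membership_truth` (protein_id, cluster_id).
#' @export
make_genome_annotation <- function(proteome, cluster_spec = NULL,
                                   contig_length = 2e6) {
  records <- proteome$records
  if (is.null(cluster_spec)) {
    cluster_spec <- data.frame(cluster_id = character(0),
                               species_id = character(0),
                               cluster_type = character(0),
                               members = character(0),
                               stringsAsFactors = FALSE)
  }
  if (!"most_similar_known_cluster" %in% names(cluster_spec)) {
    cluster_spec$most_similar_known_cluster <- rep("", nrow(cluster_spec))
  }
  if (!"similarity_percent" %in% names(cluster_spec)) {
    cluster_spec$similarity_percent <- rep(NA_real_, nrow(cluster_spec))
  }
  all_members <- unlist(strsplit(cluster_spec$members, ";", fixed = TRUE))
  unknown <- setdiff(all_members, records$protein_id)
  if (length(unknown)) {
    stop_cyp("cluster spec references unknown proteins: ",
             paste(unknown, collapse = ", "), class = "cyp_input_error")
  }
  spacer <- 200L
  margin <- 50L
  loci <- list()
  clusters <- list()
  truth <- list()
  for (sid in unique(records$species_id)) {
    sp_rec <- records[records$species_id == sid, , drop = FALSE]
    sp_clu <- cluster_spec[cluster_spec$species_id == sid, , drop = FALSE]
    member_lists <- strsplit(sp_clu$members, ";", fixed = TRUE)
    clustered <- unlist(member_lists)
    if (anyDuplicated(clustered)) {
      stop_cyp("protein assigned to more than one cluster in species ", sid,
               class = "cyp_input_error")
    }
    # clusters first (members adjacent), then the rest
    ordered_ids <- c(clustered, setdiff(sp_rec$protein_id, clustered))
    pos <- 1L
    starts <- ends <- setNames(integer(length(ordered_ids)), ordered_ids)
    for (pid in ordered_ids) {
      aa_len <- nchar(sp_rec$sequence[sp_rec$protein_id == pid])
      glen <- 3L * aa_len + 3L
      starts[pid] <- pos
      ends[pid] <- pos + glen - 1L
      pos <- pos + glen + spacer
    }
    if (pos > contig_length) {
      stop_cyp("genes exceed contig length for species ", sid,
               class = "cyp_generation_error")
    }
    loci[[sid]] <- data.frame(
      protein_id = ordered_ids, species_id = sid, contig = "chr1",
      start = unname(starts), end = unname(ends),
      strand = rep("+", length(ordered_ids)), stringsAsFactors = FALSE)
    for (ci in seq_len(nrow(sp_clu))) {
      mem <- member_lists[[ci]]
      clusters[[length(clusters) + 1L]] <- data.frame(
        cluster_id = sp_clu$cluster_id[ci], species_id = sid,
        contig = "chr1",
        start = max(1L, min(starts[mem]) - margin),
        end = max(ends[mem]) + margin,
        cluster_type = sp_clu$cluster_type[ci],
        most_similar_known_cluster = sp_clu$most_similar_known_cluster[ci],
        similarity_percent = sp_clu$similarity_percent[ci],
        stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        protein_id = mem, cluster_id = sp_clu$cluster_id[ci],
        stringsAsFactors = FALSE)
    }
  }
  bind <- function(x, proto) {
    if (length(x)) do.call(rbind, c(x, list(make.row.names = FALSE))) else proto
  }
  list(
    loci = bind(loci, data.frame(protein_id = character(0),
                                 species_id = character(0),
                                 contig = character(0), start = integer(0),
                                 end = integer(0), strand = character(0))),
    clusters = bind(clusters,
                    data.frame(cluster_id = character(0),
                               species_id = character(0),
                               contig = character(0), start = integer(0),
                               end = integer(0), cluster_type = character(0),
                               most_similar_known_cluster = character(0),
                               similarity_percent = numeric(0))),
    membership_truth = bind(truth, data.frame(protein_id = character(0),
                                              cluster_id = character(0))))
}

#' Default ground-truthed study bundle
#'
#' The standard synthetic study: 4 reference families with 2 subfamilies
#' each (400-aa references), 3 species with 10 planted P450s each at
#' identities 62–90% (at least 5 points clear of both nomenclature
#' thresholds), 2 decoys and 1 fragment per species, and 6 BGCs (2 per
#' species) together holding 9 of the planted P450s.
#'
#' @param seed integer seed.
#' @param scheme a [scoring_scheme()].
#' @return list with `refdb`, `proteome` (records + truth), `annotation`
#'   (loci, clusters, membership truth).
#' @export
default_truth_bundle <- function(seed = 1L, scheme = scoring_scheme()) {
  refdb <- make_reference_db(4L, 2L, 400L, seed = seed, scheme = scheme)
  ref_names <- refdb$entries$name
  identities <- c(90, 85, 80, 76, 72, 68, 66, 64, 63, 62)
  specs <- lapply(1:3, function(s) {
    species_spec(sprintf("sp%02d", s),
                 planted_refs = ref_names[(seq_len(10) + s) %% length(ref_names) + 1L],
                 planted_identities = identities,
                 n_decoys = 2L, n_fragments = 1L)
  })
  proteome <- make_proteome(specs, refdb, seed = seed + 1L, scheme = scheme)
  cluster_types <- c("NRPS, T1PKS", "terpene")
  cluster_spec <- do.call(rbind, lapply(1:3, function(s) {
    sid <- sprintf("sp%02d", s)
    data.frame(
      cluster_id = sprintf("%s_c%d", sid, 1:2),
      species_id = sid,
      cluster_type = cluster_types,
      members = c(paste(sprintf("%s_p%03d", sid, 1:2), collapse = ";"),
                  sprintf("%s_p%03d", sid, 3L)),
      stringsAsFactors = FALSE)
  }))
  annotation <- make_genome_annotation(proteome, cluster_spec)
  list(refdb = refdb, proteome = proteome, annotation = annotation)
}

#' Write a truth bundle to a run directory
#'
#' Serializes a [default_truth_bundle()]-shaped object as plain text:
#' `reference.fasta`, `proteome.fasta`, `loci.tsv`, `clusters.tsv`,
#' `truth.tsv`, `membership_truth.tsv`.
#'
#' @param bundle result of [default_truth_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_reference_db(bundle$refdb, file.path(dir, "reference.fasta"))
  aa <- Biostrings::AAStringSet(bundle$proteome$records$sequence)
  names(aa) <- paste(bundle$proteome$records$protein_id,
                     bundle$proteome$records$species_id)
  Biostrings::writeXStringSet(aa, file.path(dir, "proteome.fasta"),
                              width = 70L)
  write_tsv_file(bundle$annotation$loci, file.path(dir, "loci.tsv"))
  write_tsv_file(bundle$annotation$clusters, file.path(dir, "clusters.tsv"))
  write_tsv_file(bundle$proteome$truth, file.path(dir, "truth.tsv"))
  write_tsv_file(bundle$annotation$membership_truth,
                 file.path(dir, "membership_truth.tsv"))
  invisible(dir)
}
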