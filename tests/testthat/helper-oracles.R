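# Independent oracles and shared fixtures for the test suite.

# Exhaustive global-alignment oracle: enumerates every monotone alignment
# path (no dynamic programming) and scores it with affine gap costs
# (a gap run of length L costs open + L * extend, terminal runs
# included). Exponential; only for short sequences.
oracle_align_score <- function(a, b, scheme = scoring_scheme()) {
  S <- scheme$matrix
  open <- scheme$gap_open
  ext <- scheme$gap_extend
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(A)
  nb <- length(B)
  rec <- function(i, j, last) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb) {
      best <- max(best, S[A[i], B[j]] + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= na) {
      best <- max(best,
                  -(if (last == 1L) ext else open + ext) + rec(i + 1L, j, 1L))
    }
    if (j <= nb) {
      best <- max(best,
                  -(if (last == 2L) ext else open + ext) + rec(i, j + 1L, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# Quadratic all-pairs interval-overlap oracle for BGC membership.
oracle_memberships <- function(loci, clusters, rule = "any_overlap") {
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    for (j in seq_len(nrow(clusters))) {
      if (loci$species_id[i] != clusters$species_id[j] ||
          loci$contig[i] != clusters$contig[j]) next
      ov <- min(loci$end[i], clusters$end[j]) -
        max(loci$start[i], clusters$start[j]) + 1L
      hit <- if (rule == "contained") {
        loci$start[i] >= clusters$start[j] && loci$end[i] <= clusters$end[j]
      } else {
        ov >= 1L
      }
      if (hit) {
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = loci$protein_id[i],
          cluster_id = clusters$cluster_id[j],
          overlap_bases = ov, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(protein_id = character(0), cluster_id = character(0),
                      overlap_bases = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$protein_id, out$cluster_id), , drop = FALSE]
}

# Brute-force agglomerative merge oracle: linkage distances recomputed
# from the original element-level distance matrix at every step (no
# Lance-Williams updates), same min-distance / smallest-label-set rule.
oracle_merge_sequence <- function(m, linkage = "average") {
  d0 <- as.matrix(stats::dist(m, method = "euclidean"))
  clusters <- lapply(rownames(m), identity)
  out <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in seq((i + 1L), length(clusters))) {
        vals <- d0[clusters[[i]], clusters[[j]], drop = FALSE]
        dv <- switch(linkage, single = min(vals), complete = max(vals),
                     average = mean(vals))
        key <- paste(sort(c(clusters[[i]], clusters[[j]])), collapse = ",")
        if (is.null(best) || dv < best$d - 1e-12 ||
            (abs(dv - best$d) <= 1e-12 && key < best$key)) {
          best <- list(i = i, j = j, d = dv, key = key)
        }
      }
    }
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    out[[length(out) + 1L]] <- data.frame(members = best$key,
                                          height = best$d,
                                          stringsAsFactors = FALSE)
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  do.call(rbind, out)
}

# merge table of hierarchical_cluster() reduced to the oracle's shape
impl_merge_sequence <- function(clust_axis) {
  m <- clust_axis$merges
  data.frame(
    members = vapply(seq_len(nrow(m)), function(i) {
      paste(sort(c(strsplit(m$cluster_a[i], ",", fixed = TRUE)[[1]],
                   strsplit(m$cluster_b[i], ",", fixed = TRUE)[[1]])),
            collapse = ",")
    }, ""),
    height = m$height, stringsAsFactors = FALSE)
}

# random amino-acid sequence over the 20 standard residues
random_seq <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"),
               len, replace = TRUE), collapse = "")
}

# mutate exactly k positions of a sequence (each to a different residue)
mutate_k <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  pos <- sample(seq_along(chars), k)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A","C","D","E","F","G","H","I","K","L",
                                 "M","N","P","Q","R","S","T","V","W","Y"),
                               chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

# small shared reference database, built once per test run
test_refdb <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- make_reference_db(n_families = 3L,
                                  subfamilies_per_family = 2L,
                                  seq_length = 300L, seed = 42L)
    }
    cache
  }
})

# random loci + cluster tables on a toy genome (coordinates only)
random_toy_genome <- function(n_genes = 8L, n_clusters = 3L,
                              n_species = 2L, genome_len = 10000L) {
  sp <- sprintf("sp%d", sample.int(n_species, n_genes, replace = TRUE))
  gs <- sample.int(genome_len - 600L, n_genes) + 0L
  loci <- data.frame(
    protein_id = sprintf("g%02d", seq_len(n_genes)),
    species_id = sp, contig = "chr1",
    start = gs, end = gs + sample(300:600, n_genes, replace = TRUE),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    stringsAsFactors = FALSE)
  cs <- sample.int(genome_len - 2000L, n_clusters) + 0L
  clusters <- data.frame(
    cluster_id = sprintf("c%02d", seq_len(n_clusters)),
    species_id = sprintf("sp%d", sample.int(n_species, n_clusters,
                                            replace = TRUE)),
    contig = "chr1",
    start = cs, end = cs + sample(800:2000, n_clusters, replace = TRUE),
    cluster_type = sample(c("NRPS", "terpene", "NRPS, T1PKS"),
                          n_clusters, replace = TRUE),
    most_similar_known_cluster = "", similarity_percent = NA_real_,
    stringsAsFactors = FALSE)
  list(loci = loci, clusters = clusters)
}
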