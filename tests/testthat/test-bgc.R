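write_loci_tsv <- function(df) {
  p <- tempfile(fileext = ".tsv")
  write_tsv_file(df, p)
  p
}

toy_loci <- data.frame(
  protein_id = c("g1", "g2"), species_id = "sp1", contig = "chr1",
  start = c(100L, 1001L), end = c(500L, 1500L), strand = c("+", "-"),
  stringsAsFactors = FALSE)

toy_clusters <- data.frame(
  cluster_id = "c1", species_id = "sp1", contig = "chr1",
  start = 1L, end = 1000L, cluster_type = "NRPS",
  most_similar_known_cluster = "", similarity_percent = NA_real_,
  stringsAsFactors = FALSE)

test_that("loaders validate coordinates, strands and ids with context", {
  p <- write_loci_tsv(toy_loci)
  got <- load_gene_loci(p)
  expect_identical(got$protein_id, c("g1", "g2"))
  bad <- toy_loci; bad$start[2] <- 2000L
  expect_error(load_gene_loci(write_loci_tsv(bad)), "line 2",
               class = "cyp_parse_error")
  bad <- toy_loci; bad$strand[1] <- "?"
  expect_error(load_gene_loci(write_loci_tsv(bad)), "strand",
               class = "cyp_parse_error")
  bad <- rbind(toy_loci, toy_loci[1, ])
  expect_error(load_gene_loci(write_loci_tsv(bad)), "duplicate",
               class = "cyp_parse_error")
  # cluster tables: TSV and JSON dialects agree
  pt <- tempfile(fileext = ".tsv")
  write_tsv_file(toy_clusters, pt)
  pj <- tempfile(fileext = ".json")
  jsonlite::write_json(toy_clusters, pj, auto_unbox = FALSE, na = "null")
  ct <- load_bgc_table(pt)
  cj <- load_bgc_table(pj)
  expect_identical(ct$cluster_id, cj$cluster_id)
  expect_identical(ct$start, cj$start)
  bad <- toy_clusters; bad$end <- 0L
  pb <- tempfile(fileext = ".tsv")
  write_tsv_file(bad, pb)
  expect_error(load_bgc_table(pb), "line 1", class = "cyp_parse_error")
  # empty file with header loads as an empty list
  pe <- tempfile(fileext = ".tsv")
  write_tsv_file(toy_clusters[0, ], pe)
  expect_identical(nrow(load_bgc_table(pe)), 0L)
})

test_that("GFF3 loci import carries ids and coordinates", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t100\t500\t.\t+\t.\tID=g1",
    "chr1\ttoy\tgene\t1001\t1500\t.\t-\t.\tID=g2"), p)
  got <- load_gene_loci(p, species_id = "sp1")
  expect_identical(got$protein_id, c("g1", "g2"))
  expect_identical(got$start, c(100L, 1001L))
  expect_identical(got$species_id, c("sp1", "sp1"))
  expect_error(load_gene_loci(p), class = "cyp_input_error")
})

test_that("zero-based half-open coordinates convert to 1-based inclusive", {
  df <- data.frame(start = c(0L, 99L), end = c(500L, 200L))
  got <- from_zero_based(df)
  expect_identical(got$start, c(1L, 100L))
  expect_identical(got$end, c(500L, 200L))
})

test_that("membership follows the overlap rule on fixed intervals", {
  memb <- p450s_in_clusters(toy_loci, toy_clusters)
  expect_identical(memb$protein_id, "g1")  # g2 starts 1 base past the end
  expect_identical(memb$overlap_bases, 401L)
  # containment rule: g1 [100,500] lies inside [1,1000]
  within <- p450s_in_clusters(toy_loci, toy_clusters, rule = "contained")
  expect_identical(within$protein_id, "g1")
  straddle <- toy_loci; straddle$end[1] <- 1200L
  expect_identical(nrow(p450s_in_clusters(straddle, toy_clusters,
                                          rule = "contained")), 0L)
  expect_identical(nrow(p450s_in_clusters(straddle, toy_clusters)), 1L)
  expect_identical(nrow(p450s_in_clusters(toy_loci[0, ], toy_clusters)), 0L)
})

test_that("membership equals the quadratic oracle on random toy genomes", {
  set.seed(83)
  for (rep in 1:12) {
    g <- random_toy_genome()
    for (rule in c("any_overlap", "contained")) {
      got <- p450s_in_clusters(g$loci, g$clusters, rule = rule)
      want <- oracle_memberships(g$loci, g$clusters, rule = rule)
      expect_identical(got$protein_id, want$protein_id,
                       info = paste(rep, rule))
      expect_identical(got$cluster_id, want$cluster_id)
      if (rule == "any_overlap") {
        expect_identical(got$overlap_bases, want$overlap_bases)
      }
    }
  }
})

test_that("cluster type tallies key on the verbatim hybrid string", {
  inv <- load_bgc_p450_inventory()
  tal <- tally_cluster_types(data.frame(cluster_type = inv$cluster_type))
  count_of <- function(t) tal$count[tal$cluster_type == t]
  expect_identical(count_of("NRPS, T1PKS"), 9L)
  expect_identical(count_of("terpene"), 5L)
  expect_identical(count_of("bacteriocin"), 3L)
  expect_identical(nrow(tal), 10L)  # hybrids count as their own types
  expect_identical(sum(tal$count), 27L)
  # invariance under reordering
  tal2 <- tally_cluster_types(
    data.frame(cluster_type = rev(inv$cluster_type)))
  expect_identical(tal, tal2)
  expect_identical(nrow(tally_cluster_types(toy_clusters[0, ])), 0L)
})

test_that("family breakdown reproduces the published shares", {
  inv <- load_bgc_p450_inventory()
  memb <- data.frame(p450_family = vapply(inv$p450_name, family_token, ""))
  brk <- bgc_family_breakdown(memb)
  expect_identical(nrow(brk), 6L)
  expect_identical(brk$family[1], "CYP110")
  expect_identical(brk$count[1], 17L)
  expect_equal(brk$share_percent[1], 63)
  expect_equal(brk$share_percent[brk$family == "CYP213"], 15)
  expect_equal(brk$share_percent[brk$family == "CYP120"], 11)
  expect_identical(sum(brk$count), nrow(memb))
  expect_true(abs(sum(brk$share_percent) - 100) <= 1)
  single <- bgc_family_breakdown(data.frame(p450_family = "CYP501"))
  expect_equal(single$share_percent, 100)
})

test_that("the membership report joins cluster context and keeps blanks", {
  cl <- rbind(toy_clusters,
              data.frame(cluster_id = "c2", species_id = "sp1",
                         contig = "chr1", start = 2000L, end = 3000L,
                         cluster_type = "NRPS",
                         most_similar_known_cluster = "Anabaenopeptin NZ 857/nostamide A",
                         similarity_percent = 100,
                         stringsAsFactors = FALSE))
  memb <- data.frame(protein_id = c("g1", "g3"),
                     cluster_id = c("c1", "c2"),
                     p450_name = c("CYP110K6", "CYP110AH1"),
                     stringsAsFactors = FALSE)
  rep <- similarity_report(cl, memb)
  expect_identical(rep$p450_name, c("CYP110K6", "CYP110AH1"))
  expect_identical(rep$most_similar_known_cluster[1], "")
  expect_true(is.na(rep$similarity_percent[1]))
  expect_identical(rep$most_similar_known_cluster[2],
                   "Anabaenopeptin NZ 857/nostamide A")
  expect_equal(rep$similarity_percent[2], 100)
  bad <- data.frame(protein_id = "g1", cluster_id = "nope")
  expect_error(similarity_report(cl, bad), "nope",
               class = "cyp_input_error")
  expect_identical(nrow(similarity_report(cl, memb[0, ])), 0L)
})
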