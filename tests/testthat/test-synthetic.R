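test_that("reference generation is deterministic and respects the identity ceiling", {
  db1 <- make_reference_db(2L, 1L, 200L, seed = 7L)
  db2 <- make_reference_db(2L, 1L, 200L, seed = 7L)
  expect_identical(db1$entries, db2$entries)
  # inter-family identities measured below the ceiling
  id <- global_align(db1$entries$sequence[1],
                     db1$entries$sequence[2])$identity_percent
  expect_lt(id, 30)
  # labels parse through the nomenclature grammar
  for (nm in db1$entries$name) {
    expect_silent(parse_p450_name(nm))
  }
})

test_that("subfamily exemplars sit at 60-90% identity to their founder", {
  db <- test_refdb()  # 3 families x 2 subfamilies
  fams <- vapply(db$entries$name, family_token, "")
  for (f in unique(fams)) {
    rows <- which(fams == f)
    founder <- db$entries$sequence[rows[1]]
    for (r in rows[-1]) {
      id <- global_align(founder, db$entries$sequence[r])$identity_percent
      expect_gte(id, 58)  # target band 60-90, +/-2 generator tolerance
      expect_lte(id, 92)
    }
  }
})

test_that("mutation hits its identity target within tolerance", {
  set.seed(89)
  base <- random_seq(300)
  expect_identical(as.character(mutate_to_identity(base, 100, seed = 1)),
                   base)
  m70a <- mutate_to_identity(base, 70, seed = 2)
  m70b <- mutate_to_identity(base, 70, seed = 2)
  expect_identical(as.character(m70a), as.character(m70b))
  measured <- global_align(base, as.character(m70a))$identity_percent
  expect_gte(measured, 68)
  expect_lte(measured, 72)
  expect_error(mutate_to_identity(base, 5, seed = 3))
})

test_that("generated proteomes carry a complete, triage-consistent truth table", {
  db <- test_refdb()
  spec <- species_spec("spA",
                       planted_refs = db$entries$name[c(1, 3, 5, 1, 3)],
                       planted_identities = c(90, 80, 70, 65, 62),
                       n_decoys = 2L, n_fragments = 1L)
  pr <- make_proteome(list(spec), db, seed = 13L)
  expect_identical(nrow(pr$records), 8L)
  expect_identical(nrow(pr$truth), 8L)
  expect_setequal(pr$truth$protein_id, pr$records$protein_id)
  tri <- triage_proteome(pr$records)
  merged <- merge(tri$records, pr$truth, by = "protein_id")
  expect_identical(merged$category.x, merged$category.y)
  expect_identical(unname(tri$counts), c(5L, 1L, 2L))
  # zero-species and unknown-reference edge cases
  empty <- make_proteome(list(), db, seed = 1L)
  expect_identical(nrow(empty$records), 0L)
  bad <- species_spec("spB", "CYP999A1", 80)
  expect_error(make_proteome(list(bad), db, seed = 1L),
               class = "cyp_input_error")
})

test_that("high-identity planted sets recover their planted subfamilies", {
  db <- test_refdb()
  spec <- species_spec("spC",
                       planted_refs = db$entries$name[c(2, 4, 6)],
                       planted_identities = c(85, 78, 72))
  pr <- make_proteome(list(spec), db, seed = 17L)
  cls <- classify_proteome(pr$records, db)
  merged <- merge(cls$assignments, pr$truth, by = "protein_id")
  expect_identical(merged$family, merged$true_family)
  expect_identical(merged$subfamily, merged$true_subfamily)
  expect_true(all(merged$status == "known_subfamily"))
})

test_that("genome annotation plants clusters whose membership is exact", {
  db <- test_refdb()
  spec <- species_spec("spD",
                       planted_refs = db$entries$name[c(1, 2, 3, 4, 5)],
                       planted_identities = rep(80, 5))
  pr <- make_proteome(list(spec), db, seed = 19L)
  cs <- data.frame(cluster_id = c("k1", "k2"), species_id = "spD",
                   cluster_type = c("NRPS, T1PKS", "terpene"),
                   members = c("spD_p001;spD_p002", "spD_p004"),
                   stringsAsFactors = FALSE)
  ann <- make_genome_annotation(pr, cs)
  memb <- p450s_in_clusters(ann$loci, ann$clusters)
  expect_identical(sort(paste(memb$protein_id, memb$cluster_id)),
                   sort(paste(ann$membership_truth$protein_id,
                              ann$membership_truth$cluster_id)))
  expect_identical(nrow(memb), 3L)
  # type tallies match the cluster spec
  tal <- tally_cluster_types(ann$clusters)
  expect_setequal(tal$cluster_type, c("NRPS, T1PKS", "terpene"))
  # no clusters: empty membership
  ann0 <- make_genome_annotation(pr, NULL)
  expect_identical(nrow(ann0$clusters), 0L)
  expect_identical(nrow(p450s_in_clusters(ann0$loci, ann0$clusters)), 0L)
  # overflow and unknown-member errors
  expect_error(make_genome_annotation(pr, cs, contig_length = 1000),
               class = "cyp_generation_error")
  csbad <- cs; csbad$members[1] <- "spD_p099"
  expect_error(make_genome_annotation(pr, csbad),
               class = "cyp_input_error")
})
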