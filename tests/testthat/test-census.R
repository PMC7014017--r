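test_that("census counts the published BGC-resident P450 inventory", {
  inv <- load_bgc_p450_inventory()
  asg <- data.frame(species_id = "cyano",
                    family = vapply(inv$p450_name, family_token, ""),
                    subfamily = vapply(inv$p450_name, subfamily_token, ""),
                    stringsAsFactors = FALSE)
  cen <- build_census(asg)
  expect_identical(ncol(cen$family), 6L)
  counts <- setNames(as.integer(cen$family["cyano", ]),
                     colnames(cen$family))
  expect_identical(counts[["CYP110"]], 17L)
  expect_identical(counts[["CYP213"]], 4L)
  expect_identical(counts[["CYP120"]], 3L)
  expect_identical(counts[["CYP1011"]], 1L)
  expect_identical(counts[["CYP1185"]], 1L)
  expect_identical(counts[["CYP197"]], 1L)
  expect_identical(dominant_families(cen, 1)$family, "CYP110")
  # one species: every family it has is trivially conserved
  expect_setequal(conserved_families(cen), colnames(cen$family))
})

test_that("census conserves totals and handles empty input", {
  empty <- build_census(data.frame(species_id = character(0),
                                   family = character(0)))
  expect_identical(dim(empty$family), c(0L, 0L))
  asg <- data.frame(
    species_id = rep(c("s1", "s2", "s3"), times = c(4, 3, 2)),
    family = c("CYP501", "CYP501", "CYP502", "CYP503",
               "CYP501", "CYP502", "CYP502",
               "CYP501", "CYP504"),
    stringsAsFactors = FALSE)
  cen <- build_census(asg)
  expect_identical(sum(cen$family), nrow(asg))
  expect_identical(unname(rowSums(cen$family)[c("s1", "s2", "s3")]),
                   c(4, 3, 2))
  # CYP501 planted in all species is the only conserved family
  expect_identical(conserved_families(cen), "CYP501")
  expect_identical(dominant_families(cen, 2)$family, c("CYP501", "CYP502"))
})

test_that("diversity percentages follow the published formulas", {
  expect_equal(p450_diversity_percentage(36, 341, 114), 0.09)
  expect_equal(p450_diversity_percentage(13, 507, 128), 0.02)
  expect_equal(p450_diversity_percentage(77, 1784, 60), 0.07)
  expect_equal(p450_diversity_percentage(144, 1625, 48), 0.18)
  expect_equal(p450_diversity_percentage(1, 1, 1), 100.00)
  expect_equal(gene_cluster_diversity_percentage(73, 770, 114), 0.08)
  expect_equal(gene_cluster_diversity_percentage(33, 1098, 128), 0.02)
  expect_equal(gene_cluster_diversity_percentage(18, 898, 60), 0.03)
  expect_equal(gene_cluster_diversity_percentage(159, 1461, 48), 0.23)
  expect_equal(gene_cluster_diversity_percentage(1, 1, 1), 100.00)
  expect_error(p450_diversity_percentage(5, 0, 3),
               class = "cyp_domain_error")
  expect_error(gene_cluster_diversity_percentage(5, 10, 0),
               class = "cyp_domain_error")
})

test_that("doubling the species count exactly halves both percentages", {
  set.seed(53)
  for (rep in 1:10) {
    f <- sample(1:200, 1); p <- sample(f:2000, 1); s <- sample(1:100, 1)
    a <- 100 * f / (p * s)
    b <- 100 * f / (p * (2 * s))
    expect_equal(b, a / 2)
    # and the rounded public function agrees with direct evaluation
    expect_equal(p450_diversity_percentage(f, p, s), round_half_up(a, 2))
  }
})

test_that("averages and shares use integer half-up rounding", {
  expect_equal(unname(averages_and_shares(341, 114, 770, 27)), c(3, 7, 8))
  expect_equal(unname(averages_and_shares(507, 128, 1098, 112)),
               c(4, 9, 22))
  expect_equal(unname(averages_and_shares(1784, 60, 898, 204)),
               c(30, 15, 11))
  expect_equal(unname(averages_and_shares(1625, 48, 1461, 554)),
               c(34, 30, 34))
  expect_equal(unname(averages_and_shares(10, 10, 0, 0)), c(1, 0, 0))
  expect_error(averages_and_shares(10, 10, 5, 11),
               class = "cyp_domain_error")
})

test_that("the comparative summary recomputes every derived row", {
  summaries <- comparative_summaries()
  tab <- summary_table(summaries)
  col <- function(taxon, feature) {
    tab[tab$feature == feature, taxon]
  }
  expect_identical(col("Cyanobacteria", "p450_div_pct"), "0.09")
  expect_identical(col("Streptomyces", "cluster_div_pct"), "0.23")
  expect_identical(col("Mycobacteria", "avg_p450"), "30")
  expect_identical(col("Bacillus", "pct_in_bgc"), "22")
  expect_identical(names(tab), c("feature", "Cyanobacteria", "Bacillus",
                                 "Mycobacteria", "Streptomyces"))
  one <- summary_table(summaries["Cyanobacteria"])
  expect_identical(ncol(one), 2L)
  # synthetic counts round-trip against direct formula evaluation
  s <- diversity_summary("toy", 5, 40, 8, 12, 20, 6, 10)
  expect_equal(s$p450_div_pct, round_half_up(100 * 8 / (40 * 5), 2))
  expect_equal(s$cluster_div_pct, round_half_up(100 * 6 / (20 * 5), 2))
  expect_equal(s$avg_p450, round_half_up(40 / 5))
  expect_equal(s$pct_in_bgc, 25)
})
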