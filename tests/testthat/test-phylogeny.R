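test_that("identity distances are symmetric, zero-diagonal and consistent", {
  set.seed(73)
  s1 <- random_seq(80)
  s2 <- mutate_k(s1, 20L)
  seqs <- c(x = s1, y = s1, z = s2)
  d <- distance_matrix(seqs)
  expect_equal(d["x", "y"], 0)
  expect_equal(diag(d), c(x = 0, y = 0, z = 0))
  expect_equal(d, t(d))
  expect_true(all(d >= 0 & d <= 1))
  # entries match an independent recomputation through the aligner
  expect_equal(d["x", "z"],
               1 - global_align(s1, s2)$identity_percent / 100)
  expect_error(distance_matrix(c(a = s1, a = s2, b = s1)),
               class = "cyp_input_error")
  expect_error(distance_matrix(c(a = s1, b = s2)),
               class = "cyp_input_error")
})

test_that("three-taxon NJ solves the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[["A"]], 1)  # (dAB + dAC - dBC) / 2
  expect_equal(bl[["B"]], 2)
  expect_equal(bl[["C"]], 3)
})

test_that("NJ recovers additive 4- and 5-taxon trees exactly", {
  # 4 taxa: cherries (A,B) and (C,D) joined by an internal edge of 0.7
  d4 <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d4["A", "B"] <- 3.0; d4["C", "D"] <- 4.0
  d4["A", "C"] <- 3.2; d4["A", "D"] <- 4.2
  d4["B", "C"] <- 4.2; d4["B", "D"] <- 5.2
  d4 <- d4 + t(d4)
  tr4 <- nj_tree(d4)
  expect_equal(max(abs(as.matrix(stats::cophenetic(tr4))[rownames(d4),
                                                         colnames(d4)] - d4)),
               0, tolerance = 1e-9)
  truth4 <- ape::unroot(ape::read.tree(
    text = "((A:1,B:2):0.7,(C:1.5,D:2.5):0);"))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr4), truth4)), 0)

  # 5 taxa: caterpillar with internal edges 0.6 and 0.8
  lab <- LETTERS[1:5]
  d5 <- matrix(0, 5, 5, dimnames = list(lab, lab))
  d5["A", "B"] <- 2.5; d5["A", "C"] <- 3.6; d5["A", "D"] <- 3.6
  d5["A", "E"] <- 4.6; d5["B", "C"] <- 4.1; d5["B", "D"] <- 4.1
  d5["B", "E"] <- 5.1; d5["C", "D"] <- 4.0; d5["C", "E"] <- 5.0
  d5["D", "E"] <- 3.4
  d5 <- d5 + t(d5)
  tr5 <- nj_tree(d5)
  expect_equal(max(abs(as.matrix(stats::cophenetic(tr5))[lab, lab] - d5)),
               0, tolerance = 1e-9)
  truth5 <- ape::unroot(ape::read.tree(
    text = "((A:1,B:1.5):0.6,C:2,(D:1.2,E:2.2):0.8);"))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr5), truth5)), 0)
})

test_that("NJ output is isomorphic under label permutation", {
  set.seed(79)
  lab <- paste0("t", 1:5)
  m <- matrix(stats::runif(25, 0.2, 1), 5, 5, dimnames = list(lab, lab))
  d <- (m + t(m)) / 2
  diag(d) <- 0
  t1 <- nj_tree(d)
  perm <- sample(5)
  t2 <- nj_tree(d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(t1),
                                             ape::unroot(t2))), 0)
  expect_error(nj_tree(m), class = "cyp_input_error")  # not symmetric
  dn <- d; dn[1, 2] <- dn[2, 1] <- -0.1
  expect_error(nj_tree(dn), class = "cyp_input_error")
})

test_that("family grouping score detects monophyly on bipartitions", {
  tr <- ape::read.tree(text = "((a1:1,a2:1):1,(b1:1,b2:1):1);")
  fam <- c(a1 = "FA", a2 = "FA", b1 = "FB", b2 = "FB")
  expect_equal(family_grouping_score(tr, fam), 1.0)
  # one family intact, one split across the tree, singleton excluded
  tr2 <- ape::read.tree(text = "(((a1:1,a2:1):1,b1:1):1,(c1:1,b2:1):1);")
  fam2 <- c(a1 = "FA", a2 = "FA", b1 = "FB", b2 = "FB", c1 = "FC")
  expect_equal(family_grouping_score(tr2, fam2), 0.5)
  # invariant under leaf renaming that preserves membership
  tr3 <- tr2
  tr3$tip.label <- paste0("x_", tr3$tip.label)
  names(fam2) <- paste0("x_", names(fam2))
  expect_equal(family_grouping_score(tr3, fam2), 0.5)
  expect_error(family_grouping_score(tr, fam[1:3]),
               class = "cyp_input_error")
  # no multi-member family: undefined
  expect_true(is.na(family_grouping_score(
    tr, c(a1 = "F1", a2 = "F2", b1 = "F3", b2 = "F4"))))
})
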