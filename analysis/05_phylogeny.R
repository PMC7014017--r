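# Neighbor-joining tree of the classified synthetic P450s on identity
# distances (d = 1 - identity/100), and the family-grouping score: the
# fraction of multi-member families that are monophyletic — the sanity
# check that same-family P450s group together on the tree.

source("analysis/00_setup.R")

bundle <- study_bundle()
tri <- triage_proteome(bundle$proteome$records)
assignments <- read_tsv_file(file.path(RESULTS_DIR, "assignments.tsv"))

seqs <- setNames(tri$full_length$sequence, tri$full_length$protein_id)
cat("computing", length(seqs) * (length(seqs) - 1) / 2,
    "pairwise identities for", length(seqs), "P450s...\n")
d <- distance_matrix(seqs)
write_phylip_distances(d, file.path(RESULTS_DIR, "p450_distances.phy"))

tree <- nj_tree(d)
write_newick(tree, file.path(RESULTS_DIR, "p450_nj.nwk"))

fams <- setNames(assignments$family, assignments$protein_id)
score <- family_grouping_score(tree, fams)
cat(sprintf("family grouping score: %.2f (%d families with >1 member)\n",
            score, sum(table(fams) > 1)))
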