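# Encode the census as a 3 / -3 presence/absence matrix and cluster both
# axes (Euclidean, average linkage) for heat-map export.

source("analysis/00_setup.R")

assignments <- read_tsv_file(file.path(RESULTS_DIR, "assignments.tsv"))
census <- build_census(assignments)
presence <- encode_presence(census)
cat("presence matrix:", nrow(presence), "species x", ncol(presence),
    "families;", sum(presence > 0), "present cells\n")

orders <- hierarchical_cluster(presence, linkage = "average")
export_heatmap(presence, orders,
               file.path(RESULTS_DIR, "family_presence_heatmap.tsv"))
writeLines(c(orders$rows$newick, orders$cols$newick),
           file.path(RESULTS_DIR, "heatmap_dendrograms.nwk"))
cat("row order:", paste(orders$rows$order, collapse = " "), "\n")
cat("column order:", paste(orders$cols$order, collapse = " "), "\n")
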