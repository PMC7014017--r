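# Generate the ground-truthed synthetic study: a reference database of
# named P450s, three species' proteomes with planted P450s at controlled
# identity (plus decoys and fragments), gene coordinates, and six BGCs
# with known P450 membership.

source("analysis/00_setup.R")

bundle <- study_bundle()
write_truth_bundle(bundle, file.path(RESULTS_DIR, "simulated"))

cat("reference P450s:", nrow(bundle$refdb$entries), "in",
    length(unique(bundle$refdb$entries$family)), "families\n")
cat("proteome records:", nrow(bundle$proteome$records), "across",
    length(unique(bundle$proteome$records$species_id)), "species\n")
print(table(bundle$proteome$truth$category))
cat("clusters:", nrow(bundle$annotation$clusters),
    "| planted memberships:", nrow(bundle$annotation$membership_truth), "\n")
cat("written to", file.path(RESULTS_DIR, "simulated"), "\n")
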