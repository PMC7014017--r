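# Triage the synthetic proteomes (full-length / fragment / false
# positive) and classify the full-length candidates against the named
# reference database with the >40% family / >55% subfamily rule, then
# score recovery against the planted truth.

source("analysis/00_setup.R")

bundle <- study_bundle()
tri <- triage_proteome(bundle$proteome$records)
cat("triage counts:\n")
print(tri$counts)
write_tsv_file(tri$records[, c("protein_id", "species_id", "category",
                               "reasons")],
               file.path(RESULTS_DIR, "triage.tsv"))

cls <- classify_proteome(tri$full_length, bundle$refdb)
write_tsv_file(cls$assignments, file.path(RESULTS_DIR, "assignments.tsv"))

truth <- bundle$proteome$truth
merged <- merge(cls$assignments,
                truth[truth$category == "full_length", ],
                by = "protein_id")
cat(sprintf("family recovery:    %.1f%%\n",
            100 * mean(merged$family == merged$true_family)))
cat(sprintf("subfamily recovery: %.1f%%\n",
            100 * mean(merged$subfamily == merged$true_subfamily)))
print(table(status = merged$status))
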