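# Shared settings for the analysis scripts. Each numbered script can be
# run on its own from the repository root; the synthetic study bundle is
# regenerated deterministically from RUN_SEED wherever it is needed.

suppressMessages(library(cypcensus))

RUN_SEED <- 42L
RESULTS_DIR <- "results/analysis"
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)

study_bundle <- function() default_truth_bundle(seed = RUN_SEED)
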