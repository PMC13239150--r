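# Shared settings for the analysis drivers. Each numbered script can be run
# on its own from the repository root; everything deterministic flows from
# SEED, so later scripts can regenerate the study instead of reading binary
# state.

library(pleiopc)

SEED <- 42
RESULTS_DIR <- "results"
STUDY_DIR <- file.path(RESULTS_DIR, "study")
PIPE_DIR <- file.path(RESULTS_DIR, "pipeline")

dir.create(RESULTS_DIR, showWarnings = FALSE)

# the study conditions: 8 disorders, 2000 panel SNPs, three planted
# components at scales 10/7/5 over unit Z noise, LD blocks of 5 at r2 0.8
make_study <- function() {
  model <- generate_model(n_traits = 8, n_snps = 2000, n_components = 3,
                          sparsity = 0.15, scales = c(10, 7, 5), seed = SEED)
  generate_sumstats(model, noise_sd = 1, seed = SEED + 1)
}
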