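# Shared settings for the numbered analysis drivers.
# Each driver is a thin narrative over the emodecode package: all computation
# lives in R/, so the same code paths are exercised by the test suite and by
# scripts/acceptance.R. Tables land under results/, bulky volumes under
# scratch/ (not part of the deliverable).

library(emodecode)

MASTER_SEED <- 20260927L
RESULTS_DIR <- file.path("results")
SCRATCH_DIR <- file.path("scratch", "analysis")
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(SCRATCH_DIR, showWarnings = FALSE, recursive = TRUE)

# a (seed per stage) scheme so each driver is independently reproducible
SEEDS <- derive_seeds(MASTER_SEED, 8)

write_tsv <- function(x, name) {
  path <- file.path(RESULTS_DIR, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  path
}
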