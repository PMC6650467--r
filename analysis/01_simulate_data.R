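#!/usr/bin/env Rscript
# Generate the deterministic synthetic study inputs for the downstream
# analyses: twelve pocket-distance trajectories per synthetic subtype
# (three replicates in each of four conditions, stationary open
# probabilities 0.50 / 0.005 / 0.035 / 0.045 for M1 / M2 / M3 / M4) and
# wild-type-like plus mutant-like interaction-binding tables (the mutant
# carries a 1-log-unit pKB reduction).

library(allopocket)

seed <- 1L
fix_dir <- file.path("results", "fixtures")

manifest <- make_fixture_suite(fix_dir, seed = seed)

message("wrote ", nrow(manifest), " files to ", fix_dir)
message(
  "  distance tables: ", sum(manifest$role == "distance-table"),
  " | binding tables: ", sum(manifest$role == "binding-table")
)
message("manifest (with md5 hashes): ", file.path(fix_dir, "manifest.csv"))
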