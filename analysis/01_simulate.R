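#!/usr/bin/env Rscript
# Step 1 — build the synthetic screening study.
#
# Emulates the study layout at desk scale: 20 flow-cytometry T-cell traits
# measured in one cohort (n = 3,757), of which 3 carry a true protective
# effect on the disease (OR 0.67 per SD, instrumented at R2 = 0.24 as the
# study's protective traits were), screened against a primary outcome
# (38,243 with 1,873 cases) and two rare-disease validation outcomes
# (217,288/232 and 386,783/152). Everything is written as TSV under
# results/sim/ in the same dialect the package readers consume.

suppressPackageStartupMessages(library(mrscreen))

seed <- 20260929L
out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

st <- sim_screen(
  n_exposures = 20, n_causal = 3, true_beta = log(0.67), causal_r2 = 0.24,
  outcome_shapes = list(c(38243, 1873), c(217288, 232), c(386783, 152)),
  cfg = sim_config(n_snps = 9, n_blocks = 3, n_instruments = 3),
  seed = seed
)

for (nm in names(st$exposures)) {
  write.table(st$exposures[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
for (o in seq_along(st$outcomes)) {
  write.table(st$outcomes[[o]],
              file.path(out_dir, sprintf("outcome_%d.tsv", o)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write_ld_panel(st$ld, file.path(out_dir, "ld_edges.tsv"),
               file.path(out_dir, "ld_positions.tsv"))
jsonlite::write_json(
  list(seed = seed, causal_ids = st$causal_ids,
       outcome_meta = lapply(st$outcome_meta, unclass)),
  file.path(out_dir, "study_config.json"), auto_unbox = TRUE, digits = NA)

# the named fixture suite used by the documentation
manifest <- make_fixture_suite(file.path(out_dir, "fixtures"), seed = seed)
cat(sprintf("Fixture suite: %d scenarios under %s/fixtures\n",
            nrow(manifest), out_dir))

cat(sprintf("Wrote %d exposures, %d outcomes and the LD panel to %s\n",
            length(st$exposures), length(st$outcomes), out_dir))
cat("Causal traits (ground truth):",
    paste(st$causal_ids, collapse = ", "), "\n")
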