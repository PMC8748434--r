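#!/usr/bin/env Rscript
# Simulate the three-stage study and export its raw inputs as plain text:
# per-stage/replicate contact maps (COO + BED4 bins), pooled fine-layer
# maps, gene expression, H3K27ac peaks and CTCF motifs, plus the planted
# truth used later as the recovery oracle.

source(file.path("analysis", "_common.R"))

message("Simulating three-stage study (seed ", STUDY_SEED, ") ...")
study <- get_study()
dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)

for (s in names(study$coarse_maps)) {
  for (r in seq_along(study$coarse_maps[[s]])) {
    write_contact_map(study$coarse_maps[[s]][[r]],
                      file.path(DATA_DIR, sprintf("coarse_%s_rep%d.coo", s, r)),
                      file.path(DATA_DIR, sprintf("coarse_%s_rep%d.bins.bed", s, r)))
  }
  write_contact_map(study$fine_maps[[s]],
                    file.path(DATA_DIR, sprintf("fine_%s_pooled.coo", s)),
                    file.path(DATA_DIR, sprintf("fine_%s_pooled.bins.bed", s)))
}
utils::write.table(study$tracks$expression,
                   file.path(DATA_DIR, "expression_tpm.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(study$tracks$h3k27ac[, c("chrom", "start", "end", "signal")],
                   file.path(DATA_DIR, "h3k27ac_peaks.bedgraph"),
                   sep = "\t", quote = FALSE, row.names = FALSE,
                   col.names = FALSE)
utils::write.table(study$tracks$ctcf,
                   file.path(DATA_DIR, "ctcf_motifs.bed"),
                   sep = "\t", quote = FALSE, row.names = FALSE,
                   col.names = FALSE)

ct <- study$coarse_truth
message("Planted architecture:")
message("  compartment blocks with one flipped in stage 3: bins ",
        ct$flipped_block[1], "-", ct$flipped_block[2])
message("  ", length(ct$tad_boundaries[[1]]),
        " TAD boundaries; boundary dropped in stage 2 at bin ",
        ct$dropped_boundary)
message("  ", nrow(study$fine_truth$loops[[1]]), " loops (stage 1), ",
        nrow(study$fine_truth$pei_all), " promoter-enhancer pairs planted")
message("Raw inputs under ", DATA_DIR)
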