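#!/usr/bin/env Rscript
# Fine-layer analysis at 5 kb: promoter-enhancer interaction calling,
# regulatory potential scores with differential analysis and k-means
# profiles, enhancer classification from stitched H3K27ac signal,
# loop calling with the convergent-CTCF filter, and the promoter-skipping
# fraction.

source(file.path("analysis", "_common.R"))

cfg <- study_config()
stages <- cfg$coarse$stages
study <- get_study()
ftruth <- study$fine_truth
fine_cfg <- study$fine_cfg

message("Balancing pooled fine-layer maps ...")
fbal <- lapply(stages, function(s) kr_balance(read_contact_map(
  file.path(DATA_DIR, sprintf("fine_%s_pooled.coo", s)),
  file.path(DATA_DIR, sprintf("fine_%s_pooled.bins.bed", s)),
  fine_cfg$chrom)))
names(fbal) <- stages

message("Calling promoter-enhancer interactions (FDR < 0.01, >= 15 kb) ...")
gene_map <- data.frame(gene = ftruth$genes$gene,
                       promoter_bin = ftruth$genes$tss_bin)
peis <- list(); rps <- list()
for (s in stages) {
  peis[[s]] <- call_peis(fbal[[s]], ftruth$genes$tss_bin,
                         fdr = 0.01, min_dist = 15000)
  rps[[s]] <- compute_rps(peis[[s]], gene_map, stage = s)
  planted <- ftruth$peis[[s]]
  rec <- mean(vapply(seq_len(nrow(planted)), function(k)
    any(peis[[s]]$promoter_bin == planted$promoter_bin[k] &
          abs(peis[[s]]$enhancer_bin - planted$enhancer_bin[k]) <= 1),
    logical(1)))
  message(sprintf("  %s: %d PEIs (planted recall %.2f)", s,
                  nrow(peis[[s]]), rec))
  tsv(peis[[s]], sprintf("peis_%s.tsv", s))
  tsv(rps[[s]], sprintf("rps_%s.tsv", s))
}

message("Differential RPS (|log2FC| > 1.5 and |dRPS| > 3) and clustering ...")
dyn <- character(0)
for (k in 1:2) {
  dd <- differential_rps(rps[[stages[k]]], rps[[stages[k + 1]]])
  tsv(dd, sprintf("rps_diff_%s_vs_%s.tsv", stages[k], stages[k + 1]))
  message(sprintf("  %s vs %s: %d genes with differential RPS",
                  stages[k], stages[k + 1], sum(dd$flagged)))
  dyn <- union(dyn, dd$gene[dd$flagged])
}
rps_mat <- sapply(stages, function(s) rps[[s]]$rps)
rownames(rps_mat) <- rps[[1]]$gene
if (length(dyn) >= 12) {
  cl <- cluster_profiles(rps_mat[dyn, , drop = FALSE], k = 6,
                         seed = STUDY_SEED)
  tsv(data.frame(gene = names(cl$labels), cluster = cl$labels),
      "rps_clusters.tsv")
  message("  ", length(dyn), " dynamic genes in 6 k-means profile clusters")
}

message("Enhancer classification (12.5 kb stitching, slope-1 inflection) ...")
eb <- sort(unique(unlist(lapply(peis, function(p) p$enhancer_bin))))
pei_reg <- data.frame(chrom = fine_cfg$chrom,
                      start = (eb - 1) * fine_cfg$resolution,
                      end = eb * fine_cfg$resolution)
enh <- classify_enhancers(
  study$tracks$h3k27ac[, c("chrom", "start", "end", "signal")],
  stitch = 12500, pei_regions = pei_reg)
tsv(enh, "enhancer_classes.tsv")
message("  classes: ", paste(names(table(enh$class)), table(enh$class),
                             sep = "=", collapse = " "))

message("Loop calling (q < 0.05, 20 kb - 2 Mb) with CTCF orientation ...")
ctcf <- data.frame(bin = ftruth$ctcf_motifs$bin,
                   strand = ftruth$ctcf_motifs$strand)
for (s in stages) {
  loops <- convergent_filter(call_loops(fbal[[s]]), ctcf)
  tsv(loops, sprintf("loops_%s.tsv", s))
  message(sprintf("  %s: %d loops, %d convergent", s, nrow(loops),
                  sum(loops$ctcf_orientation == "convergent")))
}

skip <- promoter_skip_fraction(peis[[2]], ftruth$genes$tss_bin)
message(sprintf("Promoter skipping: %.1f%% of enhancers bypass their nearest promoter",
                100 * skip))
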