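test_that("simulation is a pure function of its config", {
  cfg <- sim_config(n_bins = 120, depth = 1e5, seed = 11)
  t1 <- build_truth(cfg); t2 <- build_truth(cfg)
  expect_identical(t1$tad_boundaries, t2$tad_boundaries)
  expect_identical(t1$compartment_labels, t2$compartment_labels)
  E <- build_expected_map(t1, cfg, 1)
  m1 <- sample_replicate(E, cfg, seed = 5)
  m2 <- sample_replicate(E, cfg, seed = 5)
  expect_identical(m1$mat, m2$mat)
  m3 <- sample_replicate(E, cfg, seed = 6)
  expect_false(identical(m1$mat, m3$mat))
})

test_that("sampled depth concentrates around the target", {
  cfg <- sim_config(n_bins = 150, depth = 5e5, seed = 2)
  tr <- build_truth(cfg)
  E <- build_expected_map(tr, cfg, 1)
  m <- sample_replicate(E, cfg, seed = 8)
  tot <- sum(m$mat[upper.tri(m$mat, diag = TRUE)])
  expect_lt(abs(tot - cfg$depth), 3 * sqrt(cfg$depth))
})

test_that("null architecture yields flat O/E; zero depth errors", {
  nm <- null_map(n_bins = 200, depth = 1e6, seed = 4)
  oe <- observed_over_expected(nm$balanced)
  v <- oe$mat[abs(row(oe$mat) - col(oe$mat)) <= 30]
  expect_lt(abs(mean(v, na.rm = TRUE) - 1), 0.05)
  cfg <- nm$cfg
  E <- build_expected_map(nm$truth, cfg, 1)
  expect_error(sample_replicate(E, cfg, depth = 0, seed = 1),
               "total count > 0")
})

test_that("compartment contrast of the expected map matches construction", {
  # two-state checkerboard with c = 0.5: within/cross O/E ratio is 3
  cfg <- sim_config(n_bins = 200, compartment_contrast = 0.5,
                    tad_enrichment = 0, loop_enrichment = 0,
                    pei_enrichment = 0, flip_block_stage = NA,
                    drop_boundary_stage = NA, seed = 21)
  tr <- build_truth(cfg)
  E <- build_expected_map(tr, cfg, 1)
  lab <- tr$compartment_labels[[1]]
  d <- abs(outer(seq_len(200), seq_len(200), "-"))
  decay <- (1 + d)^(-1)
  oe <- E / decay
  same <- outer(lab, lab, "==")
  off <- d > 0
  expect_equal(mean(oe[same & off]) / mean(oe[!same & off]), 3,
               tolerance = 1e-9)
})

test_that("a planted boundary flips the DI sign on the noise-free expectation", {
  cfg <- sim_config(n_bins = 200, compartment_contrast = 0,
                    loop_enrichment = 0, pei_enrichment = 0,
                    flip_block_stage = NA, drop_boundary_stage = NA,
                    seed = 31)
  tr <- build_truth(cfg)
  E <- build_expected_map(tr, cfg, 1)
  m <- contact_map(E * 1e5, make_bins(cfg$chrom, 200, cfg$resolution),
                   cfg$resolution, cfg$chrom, balanced = TRUE)
  di <- directionality_index(m)
  b <- tr$tad_boundaries[[1]]
  b <- b[b > 25 & b < 175]
  expect_true(all(di$di[b] > 0))       # domain start: downstream bias
  expect_true(all(di$di[b - 1] < 0))   # domain end: upstream bias
})

test_that("stage toggles plant recoverable compartment and boundary changes", {
  cfg <- sim_config(n_bins = 300, seed = 13)
  tr <- build_truth(cfg)
  fb <- tr$flipped_block
  expect_false(is.null(fb))
  s_flip <- cfg$stages[cfg$flip_block_stage]
  s_ref <- cfg$stages[1]
  expect_true(all(tr$compartment_labels[[s_flip]][fb[1]:fb[2]] !=
                    tr$compartment_labels[[s_ref]][fb[1]:fb[2]]))
  expect_true(all(tr$compartment_labels[[s_flip]][-(fb[1]:fb[2])] ==
                    tr$compartment_labels[[s_ref]][-(fb[1]:fb[2])]))
  expect_false(tr$dropped_boundary %in%
                 tr$tad_boundaries[[cfg$drop_boundary_stage]])
  expect_true(tr$dropped_boundary %in% tr$tad_boundaries[[1]])
})

test_that("planted CTCF anchors are convergent and decoys tandem", {
  cfg <- sim_config(n_bins = 300, seed = 17)
  tr <- build_truth(cfg)
  lp <- tr$loops[[1]]
  ann <- convergent_filter(
    data.frame(anchor_i = lp$bin_i, anchor_j = lp$bin_j),
    data.frame(bin = tr$ctcf_motifs$bin, strand = tr$ctcf_motifs$strand))
  expect_true(all(ann$ctcf_orientation == "convergent"))
  dec <- convergent_filter(
    data.frame(anchor_i = tr$decoy_pairs$bin_i,
               anchor_j = tr$decoy_pairs$bin_j),
    data.frame(bin = tr$ctcf_motifs$bin, strand = tr$ctcf_motifs$strand))
  expect_true(all(dec$ctcf_orientation != "convergent"))
})

test_that("expression couples to compartment membership when planted", {
  # beta_A > 0: A-compartment genes express higher in most seeds
  hits <- 0L
  for (sd in 1:12) {
    cfg <- sim_config(n_bins = 200, seed = sd, expr_beta_a = 1,
                      expr_beta_r = 0, flip_block_stage = NA,
                      drop_boundary_stage = NA)
    tr <- build_truth(cfg)
    trk <- simulate_tracks(tr, cfg, seed = sd + 500)
    e <- trk$expression[trk$expression$stage == cfg$stages[1] &
                          trk$expression$replicate == 1, ]
    lab <- tr$compartment_labels[[1]][tr$genes$tss_bin]
    if (stats::median(e$tpm[lab == "A"]) > stats::median(e$tpm[lab == "B"]))
      hits <- hits + 1L
  }
  expect_gte(hits, 11L)

  # beta_A = beta_R = 0: no systematic A/B difference
  cfg0 <- sim_config(n_bins = 200, seed = 3, expr_beta_a = 0, expr_beta_r = 0,
                     flip_block_stage = NA, drop_boundary_stage = NA)
  tr0 <- build_truth(cfg0)
  ps <- vapply(1:10, function(sd) {
    trk <- simulate_tracks(tr0, cfg0, seed = sd)
    e <- trk$expression[trk$expression$stage == cfg0$stages[1] &
                          trk$expression$replicate == 1, ]
    lab <- tr0$compartment_labels[[1]][tr0$genes$tss_bin]
    compare_groups_expression(e$tpm[lab == "A"], e$tpm[lab == "B"])$p
  }, numeric(1))
  expect_gt(stats::median(ps), 0.05)    # typically non-significant under null
})

test_that("super-enhancer tracks are broad and stitchable", {
  cfg <- sim_config(n_bins = 300, resolution = 5000, seed = 23)
  tr <- build_truth(cfg)
  trk <- simulate_tracks(tr, cfg)
  se_bins <- tr$enhancer_classes$enhancer_bin[tr$enhancer_classes$class == "SE"]
  for (b in se_bins) {
    memb <- trk$h3k27ac[trk$h3k27ac$enhancer_bin == b, ]
    expect_gte(nrow(memb), 5)
    gaps <- diff(sort(memb$start)) - (memb$end[1] - memb$start[1])
    expect_true(all(gaps <= 12500))
  }
  pe_bins <- tr$enhancer_classes$enhancer_bin[tr$enhancer_classes$class == "PE"]
  expect_true(all(!pe_bins %in% trk$h3k27ac$enhancer_bin))
})
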