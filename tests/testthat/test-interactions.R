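# fine-layer simulation with only promoter-anchored enrichment planted
pei_sim <- function(seed = 1, n_bins = 400, depth = 1.6e6, enrich = 4) {
  cfg <- sim_config(n_bins = n_bins, resolution = 5000,
                    compartment_contrast = 0, tad_enrichment = 0,
                    loop_enrichment = 0, pei_enrichment = enrich,
                    depth = depth, flip_block_stage = NA,
                    drop_boundary_stage = NA, seed = seed)
  truth <- build_truth(cfg)
  E <- build_expected_map(truth, cfg, 1)
  list(cfg = cfg, truth = truth,
       balanced = kr_balance(sample_replicate(E, cfg, seed = seed + 3)))
}

test_that("planted promoter-enhancer contacts are recovered, distal only", {
  s <- pei_sim(seed = 2)
  tr <- s$truth
  peis <- call_peis(s$balanced, tr$genes$tss_bin)
  planted <- tr$peis[[1]]
  rec <- mean(vapply(seq_len(nrow(planted)), function(k)
    any(peis$promoter_bin == planted$promoter_bin[k] &
          peis$enhancer_bin == planted$enhancer_bin[k]), logical(1)))
  expect_gte(rec, 0.9)
  expect_true(all(peis$distance >= 15000))
  expect_true(all(peis$q < 0.01))
  expect_true(all(peis$observed > peis$expected))
})

test_that("contacts below the minimum distance are never reported", {
  s <- pei_sim(seed = 6, n_bins = 200, depth = 8e5)
  # plant a huge proximal contact at 10 kb (2 bins at 5 kb)
  m <- s$balanced
  p <- s$truth$genes$tss_bin[5]
  m$mat[p, p + 2] <- m$mat[p + 2, p] <- max(m$mat) * 50
  peis <- call_peis(m, s$truth$genes$tss_bin)
  expect_false(any(peis$promoter_bin == p & peis$enhancer_bin == p + 2))
  expect_true(all(abs(peis$enhancer_bin - peis$promoter_bin) * 5000 >= 15000))
})

test_that("null maps keep the empirical PEI discovery rate at or below FDR", {
  nm <- null_map(n_bins = 400, depth = 1.6e6, seed = 12)
  proms <- sort(sample(20:380, 40))
  peis <- call_peis(nm$balanced, proms, fdr = 0.01)
  expect_lte(nrow(peis) / attr(peis, "n_tests"), 0.01)
})

test_that("RPS sums log10 excess contacts per gene and is additive", {
  gm <- data.frame(gene = c("g1", "g1", "g2"), promoter_bin = c(10, 11, 50))
  peis <- data.frame(promoter_bin = c(10, 11), enhancer_bin = c(30, 40),
                     distance = 1e5, observed = c(12, 102),
                     expected = c(2, 2),
                     intensity = log10(c(10, 100)), q = 1e-4)
  rps <- compute_rps(peis, gm)
  expect_equal(rps$rps[rps$gene == "g1"], 3)   # 1 + 2
  expect_equal(rps$rps[rps$gene == "g2"], 0)
  expect_equal(rps$n_peis[rps$gene == "g2"], 0)
  # additivity: splitting the PEI set and summing matches the joint call
  r1 <- compute_rps(peis[1, ], gm)
  r2 <- compute_rps(peis[2, ], gm)
  expect_equal(r1$rps + r2$rps, rps$rps)
  # near-zero excess floors at 0 with a warning
  peis$observed[1] <- peis$expected[1] + 0.5
  peis$intensity[1] <- 0
  expect_warning(compute_rps(peis, gm), "floored")
})

test_that("differential RPS requires both fold-change and absolute cutoffs", {
  mk <- function(a, b) list(
    a = data.frame(gene = "g", stage = "s1", rps = a, n_peis = 1),
    b = data.frame(gene = "g", stage = "s2", rps = b, n_peis = 1))
  x <- mk(2, 6)   # delta 4 > 3, log2FC ~ 1.54 > 1.5 -> flagged
  expect_true(differential_rps(x$a, x$b)$flagged)
  y <- mk(10, 12) # delta 2 -> never flagged
  expect_false(differential_rps(y$a, y$b)$flagged)
  z <- mk(0.5, 2) # log2FC > 1.5 but delta 1.5 -> not flagged
  expect_false(differential_rps(z$a, z$b)$flagged)
})

test_that("profile clustering is deterministic and recovers planted archetypes", {
  set.seed(9)
  up <- matrix(rep(c(0, 1, 2), 40), ncol = 3, byrow = TRUE) +
    matrix(stats::rnorm(120, 0, 0.1), ncol = 3)
  down <- matrix(rep(c(2, 1, 0), 40), ncol = 3, byrow = TRUE) +
    matrix(stats::rnorm(120, 0, 0.1), ncol = 3)
  mat <- rbind(up, down)
  rownames(mat) <- sprintf("g%02d", 1:80)
  cl <- cluster_profiles(mat, 2, seed = 4)
  truth <- rep(1:2, each = 40)
  agree <- max(mean(cl$labels == truth), mean(cl$labels == 3 - truth))
  expect_gte(agree, 0.9)
  cl2 <- cluster_profiles(mat, 2, seed = 4)
  expect_identical(cl$labels, cl2$labels)
  # duplicated rows land in the same cluster
  dup <- rbind(mat, mat[1, , drop = FALSE])
  rownames(dup)[81] <- "dup"
  cld <- cluster_profiles(dup, 2, seed = 4)
  expect_equal(unname(cld$labels["dup"]), unname(cld$labels["g01"]))
  expect_error(cluster_profiles(mat[1:3, ], 5, seed = 1), "exceeds")
})

test_that("enhancer stitching and the slope-1 inflection separate SE from RE", {
  pk <- data.frame(chrom = "chrT",
                   start = c(0, 30000, 60000, 90000, 120000),
                   end = c(1500, 31500, 61500, 91500, 121500),
                   signal = c(1, 1, 1, 1, 100))
  cls <- classify_enhancers(pk, stitch = 12500)
  expect_equal(nrow(cls), 5)   # all beyond stitch distance
  expect_equal(cls$class[cls$stitched_signal == 100], "SE")
  expect_true(all(cls$class[cls$stitched_signal == 1] == "RE"))

  # 10 kb apart stitches, 15 kb does not
  near <- data.frame(chrom = "chrT", start = c(0, 11500, 100000, 200000),
                     end = c(1500, 13000, 101500, 201500),
                     signal = c(5, 5, 3, 2))
  st <- classify_enhancers(near, stitch = 12500)
  expect_equal(nrow(st), 3)
  expect_equal(max(st$n_peaks), 2)
  far <- data.frame(chrom = "chrT", start = c(0, 16500, 100000),
                    end = c(1500, 18000, 101500), signal = c(5, 5, 3))
  expect_equal(nrow(classify_enhancers(far, stitch = 12500)), 3)

  expect_warning(out <- classify_enhancers(near[3:4, ], stitch = 12500),
                 "inflection")
  expect_true(all(out$class == "RE"))

  # PEI-contacted regions without peaks become PE; never those with peaks
  pei_reg <- data.frame(chrom = "chrT", start = c(500, 500000),
                        end = c(2000, 505000))
  full <- classify_enhancers(pk, 12500, pei_regions = pei_reg)
  expect_true("PE" %in% full$class)
  pe <- full[full$class == "PE", ]
  expect_equal(pe$start, 500000)
  expect_true(all(table(full$class[full$stitched_signal > 0]) >= 0))
})

test_that("planted enhancer classes are recovered from simulated tracks", {
  cfg <- sim_config(n_bins = 400, resolution = 5000, seed = 23)
  tr <- build_truth(cfg)
  trk <- simulate_tracks(tr, cfg)
  res <- cfg$resolution
  eb <- tr$enhancer_classes$enhancer_bin
  pei_reg <- data.frame(chrom = cfg$chrom, start = (eb - 1) * res,
                        end = eb * res)
  pred <- classify_enhancers(trk$h3k27ac[, c("chrom", "start", "end", "signal")],
                             stitch = 12500, pei_regions = pei_reg)
  hit <- vapply(seq_along(eb), function(k) {
    c0 <- (eb[k] - 1) * res; c1 <- eb[k] * res
    ov <- pred$start < c1 + 2000 & pred$end > c0 - 2000
    if (!any(ov)) return(NA)
    any(pred$class[ov] == tr$enhancer_classes$class[k])
  }, logical(1))
  expect_gte(mean(hit, na.rm = TRUE), 0.9)
})

test_that("loop calling recovers planted corner peaks and controls the null", {
  cfg <- sim_config(n_bins = 400, resolution = 5000,
                    compartment_contrast = 0, tad_enrichment = 0,
                    pei_enrichment = 0, loop_enrichment = 5, depth = 1.6e6,
                    flip_block_stage = NA, drop_boundary_stage = NA,
                    seed = 33)
  tr <- build_truth(cfg)
  E <- build_expected_map(tr, cfg, 1)
  b <- kr_balance(sample_replicate(E, cfg, seed = 35))
  loops <- call_loops(b)
  planted <- tr$loops[[1]]
  rec <- mean(vapply(seq_len(nrow(planted)), function(k)
    any(abs(loops$anchor_i - planted$bin_i[k]) <= 1 &
          abs(loops$anchor_j - planted$bin_j[k]) <= 1), logical(1)))
  expect_gte(rec, 0.9)
  expect_true(all(loops$distance >= 20000 & loops$distance <= 2e6))

  top1 <- call_loops(b, top_k = 1)
  expect_equal(nrow(top1), 1)
  expect_equal(top1$strength, max(loops$strength))

  nm <- null_map(n_bins = 400, depth = 1.6e6, seed = 44)
  nl <- call_loops(nm$balanced)
  expect_lte(nrow(nl) / attr(nl, "n_tests"), 0.05)
})

test_that("CTCF orientation inventory follows motif strands", {
  ctcf <- data.frame(bin = c(10, 50, 100, 150, 200, 250),
                     strand = c("+", "-", "-", "+", "+", "+"))
  lp <- data.frame(anchor_i = c(10, 100, 200, 300, 10),
                   anchor_j = c(50, 150, 250, 320, 100))
  ann <- convergent_filter(lp, ctcf)
  expect_equal(ann$ctcf_orientation,
               c("convergent", "divergent", "tandem", "absent", "convergent"))
  bad <- ctcf; bad$strand[2] <- "."
  expect_error(convergent_filter(lp, bad), "strand")
})

test_that("promoter skipping counts enhancers bypassing their nearest promoter", {
  peis1 <- data.frame(promoter_bin = c(10, 10), enhancer_bin = c(30, 60))
  expect_equal(promoter_skip_fraction(peis1, promoters = 10), 0)
  # enhancer 30 is nearest to promoter 26 but contacts 10 -> skipping;
  # enhancer 18 equidistant to 10 and 26 is a tie -> not skipping
  peis2 <- data.frame(promoter_bin = c(10, 10), enhancer_bin = c(30, 18))
  expect_equal(promoter_skip_fraction(peis2, promoters = c(10, 26)), 0.5)
  # planted rate recovered on a clean simulation
  s <- pei_sim(seed = 51)
  tr <- s$truth
  peis <- call_peis(s$balanced, tr$genes$tss_bin)
  planted_rate <- {
    ub <- unique(tr$peis[[1]]$enhancer_bin)
    mean(vapply(ub, function(e) {
      dmin <- min(abs(tr$genes$tss_bin - e))
      p <- tr$peis[[1]]$promoter_bin[tr$peis[[1]]$enhancer_bin == e]
      !any(abs(p - e) == dmin)
    }, logical(1)))
  }
  expect_lt(abs(promoter_skip_fraction(peis, tr$genes$tss_bin) - planted_rate),
            0.05)
})
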