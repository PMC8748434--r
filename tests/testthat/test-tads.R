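test_that("directionality index matches the chi-square-style formula", {
  expect_equal(directionality_index(di_probe_map(7, 7))$di[11], 0)
  expect_equal(directionality_index(di_probe_map(0, 20))$di[11], 20)
  expect_equal(directionality_index(di_probe_map(20, 0))$di[11], -20)
  expect_equal(directionality_index(di_probe_map(0, 0))$di[11], 0)
})

test_that("reversing the chromosome negates the DI track", {
  s <- small_sim(n_bins = 120, depth = 3e5)
  di <- directionality_index(s$balanced)
  rev_map <- s$balanced
  n <- nrow(rev_map$mat)
  rev_map$mat <- rev_map$mat[n:1, n:1]
  rev_map$mask <- rev_map$mask[n:1]
  di_rev <- directionality_index(rev_map)
  expect_equal(di$di[11:(n - 10)], -rev(di_rev$di[11:(n - 10)]),
               tolerance = 1e-9)
})

test_that("insulation score is flat on uniform maps and scale invariant", {
  u <- uniform_map(30, 2, balanced = TRUE)
  ist <- insulation_score(u)
  expect_true(all(abs(stats::na.omit(ist$is_norm)) < 1e-12))
  s <- small_sim(n_bins = 120, depth = 3e5)
  i1 <- insulation_score(s$balanced)
  m2 <- s$balanced; m2$mat <- m2$mat * 2
  i2 <- insulation_score(m2)
  expect_equal(i1$is_norm, i2$is_norm, tolerance = 1e-9)
})

test_that("planted boundaries are local insulation minima on the expectation", {
  cfg <- sim_config(n_bins = 200, compartment_contrast = 0,
                    loop_enrichment = 0, pei_enrichment = 0,
                    flip_block_stage = NA, drop_boundary_stage = NA, seed = 8)
  tr <- build_truth(cfg)
  E <- build_expected_map(tr, cfg, 1)
  m <- contact_map(E * 1e5, make_bins(cfg$chrom, 200, cfg$resolution),
                   cfg$resolution, cfg$chrom, balanced = TRUE)
  ist <- insulation_score(m)
  for (b in tr$tad_boundaries[[1]]) {
    if (b < 15 || b > 185) next
    # minimum sits on the boundary (plateau of b-1/b admissible by symmetry)
    expect_lte(abs(which.min(ist$is_norm[(b - 4):(b + 4)]) - 5), 1)
  }
})

test_that("HMM segmentation recovers planted domains and degrades gracefully", {
  # noise-free expectation: boundaries within +/-1 bin
  cfg <- sim_config(n_bins = 300, compartment_contrast = 0,
                    loop_enrichment = 0, pei_enrichment = 0,
                    flip_block_stage = NA, drop_boundary_stage = NA, seed = 5)
  tr <- build_truth(cfg)
  E <- build_expected_map(tr, cfg, 1)
  m <- contact_map(E * 1e6, make_bins(cfg$chrom, 300, cfg$resolution),
                   cfg$resolution, cfg$chrom, balanced = TRUE)
  ts <- hmm_segment(directionality_index(m))
  truth <- tr$tad_boundaries[[1]]
  interior <- truth[truth > 15 & truth < 285]
  matched <- vapply(interior, function(b)
    any(abs(ts$boundaries - b) <= 1), logical(1))
  expect_true(all(matched))

  # flat DI: single unbiased state, no domains
  flat <- uniform_map(80, 2, balanced = TRUE)
  ts0 <- hmm_segment(directionality_index(flat))
  expect_equal(nrow(ts0$domains), 0)
})

test_that("sampled replicates reach boundary F1 >= 0.8 at +/-1 bin", {
  s <- small_sim(n_bins = 300, depth = 6e5, seed = 3)
  ts <- call_tads(s$balanced, seed = 1)
  f1 <- hicdynamics:::boundary_f1(ts$boundaries, s$truth$tad_boundaries[[1]], 1)
  expect_gte(f1["f1"], 0.8)
})

test_that("domains never overlap and large domains are IS-subdivided", {
  s <- small_sim(n_bins = 300, depth = 6e5, seed = 17)
  ts <- call_tads(s$balanced, seed = 1)
  d <- ts$domains
  expect_true(all(d$end_bin >= d$start_bin))
  if (nrow(d) > 1) expect_true(all(d$start_bin[-1] > d$end_bin[-nrow(d)]))

  # a 2 Mb merged domain with a weak interior boundary is split near it
  cfg <- sim_config(n_bins = 300, compartment_contrast = 0,
                    loop_enrichment = 0, pei_enrichment = 0,
                    flip_block_stage = NA, drop_boundary_stage = NA, seed = 5)
  tr <- build_truth(cfg)
  E <- build_expected_map(tr, cfg, 1)
  b_all <- tr$tad_boundaries[[1]]
  inner <- b_all[5]
  # weaken the interior boundary so DI-HMM merges across it
  lo <- b_all[4]; hi <- b_all[6] - 1
  seg <- lo:hi
  E2 <- E
  E2[seg, seg] <- pmax(E2[seg, seg],
                       0.85 * (1 + abs(outer(seg, seg, "-")))^-1 * 2)
  m <- kr_balance(sample_replicate(E2, cfg, depth = 2e6, seed = 9))
  ts2 <- call_tads(m, max_di_tad_size = 4e5, is_prominence = 0.05, seed = 1)
  expect_true(any(abs(ts2$boundaries - inner) <= 2))
})

test_that("boundary overlap obeys its tolerance semantics", {
  expect_equal(boundary_overlap(c(100), c(100))$shared_fraction_a, 1)
  expect_equal(boundary_overlap(c(100), c(101), tol_bins = 1)$n_shared_a, 1)
  ov0 <- boundary_overlap(c(100), c(101), tol_bins = 0)
  expect_equal(ov0$n_shared_a, 0)
  expect_equal(ov0$specific_a, 100)
})

test_that("stage-specific boundary test flags lost boundaries, spares conserved", {
  set.seed(2)
  n <- 400
  base <- stats::rnorm(n)
  other <- stats::rnorm(n)
  mk_track <- function(v) {
    out <- data.frame(bin = 1:n, di = v)
    attr(out, "window") <- 10
    class(out) <- c("di_track", "data.frame")
    out
  }
  da <- mk_track(base)
  # conserved boundary: the local profile agrees across stages while the
  # genome-wide background does not -> far above the permutation null
  cons <- other; cons[190:210] <- base[190:210]
  res_c <- specific_boundary_test(da, mk_track(cons), candidates = 200,
                                  seed = 3)
  expect_equal(res_c$r_obs, 1)
  expect_false(res_c$specific)
  # planted loss: local profile uncorrelated -> indistinguishable from null
  # (flag probability is ~0.95 by construction of the cutoff)
  hits <- 0L
  for (sd in 1:20) {
    set.seed(sd + 100)
    res_s <- specific_boundary_test(da, mk_track(stats::rnorm(n)),
                                    candidates = 200, n_perm = 500, seed = sd)
    if (res_s$specific) hits <- hits + 1L
  }
  expect_gte(hits, 16L)
  # edge candidates are excluded with a warning
  expect_warning(specific_boundary_test(da, da, candidates = c(5, 200),
                                        seed = 1), "edge")
})

test_that("consensus boundaries respect the support threshold and monotonicity", {
  sets <- list(c(50, 100), c(50, 100), c(50), c(50), c(50), c(120))
  cs <- consensus_tads(sets, min_fraction = 0.5, tol_bins = 1, n_bins = 200)
  expect_true(any(abs(cs$boundaries - 50) <= 1))    # 5/6
  expect_false(any(abs(cs$boundaries - 100) <= 1))  # 2/6 dropped
  expect_false(any(abs(cs$boundaries - 120) <= 1))  # 1/6 dropped
  sets2 <- list(c(50, 100), c(50, 100), c(50, 100), c(51), c(49), c(120))
  cs2 <- consensus_tads(sets2, 0.5, 1, n_bins = 200)
  expect_true(any(abs(cs2$boundaries - 100) <= 1))  # 3/6 retained at the edge
  # raising min_fraction never adds boundaries
  for (f in c(0.3, 0.5, 0.7, 0.9)) {
    lo <- consensus_tads(sets2, f, 1, n_bins = 200)$boundaries
    hi <- consensus_tads(sets2, min(f + 0.2, 1), 1, n_bins = 200)$boundaries
    expect_true(all(vapply(hi, function(b) any(abs(lo - b) <= 1), logical(1))))
  }
  expect_error(consensus_tads(list()), "empty")
})

test_that("A/B TAD classification follows the 70% rule", {
  prof <- data.frame(bin = 1:10,
                     pc1 = c(rep(1, 8), rep(-1, 2)),
                     label = c(rep("A", 8), rep("B", 2)))
  expect_equal(classify_tad_compartment(c(1, 10), prof), "A-TAD")   # 8/10
  prof2 <- prof; prof2$label <- c(rep("A", 7), rep("B", 3))
  expect_equal(classify_tad_compartment(c(1, 10), prof2), "B-TAD")  # 7/10 not > 70%
  expect_equal(classify_tad_compartment(c(1, 10), prof2, strict = TRUE),
               "mixed")
  prof3 <- prof; prof3$label <- rep("B", 10)
  expect_equal(classify_tad_compartment(c(1, 10), prof3), "B-TAD")
  expect_equal(classify_tad_compartment(c(1, 10), prof3, strict = TRUE),
               "B-TAD")
  prof4 <- prof; prof4$label <- rep("masked", 10)
  expect_equal(classify_tad_compartment(c(1, 10), prof4), "mixed")
})

test_that("domain scores match hand counts and conserve", {
  # whole-chromosome TAD captures everything
  u <- uniform_map(10, 1, balanced = TRUE)
  whole <- consensus_tads(list(integer(0)), n_bins = 10)
  expect_equal(domain_score(u, whole)$d_score, 1)

  # 4-bin toy: TAD {1,2}; contacts (1,2)=5, (3,4)=5, (1,4)=10
  toy <- map_from_entries(4, list(c(1, 2, 5), c(3, 4, 5), c(1, 4, 10)),
                          balanced = TRUE)
  ct <- consensus_tads(list(c(3)), n_bins = 4)  # domains 1-2 and 3-4
  ds <- domain_score(toy, ct)
  expect_equal(ds$d_score[1], 5 / 20)
  expect_equal(ds$d_score[2], 5 / 20)
  expect_lte(sum(ds$d_score), 1)

  s <- small_sim(n_bins = 200, depth = 4e5)
  cs <- consensus_tads(list(s$truth$tad_boundaries[[1]]), n_bins = 200)
  expect_lte(sum(domain_score(s$balanced, cs)$d_score), 1 + 1e-12)
})

test_that("differential domain-score test flags planted changes only", {
  mk_tab <- function(vals_a, vals_b) {
    rbind(data.frame(ctad_id = "T1", stage = "s1",
                     replicate = seq_along(vals_a), d_score = vals_a),
          data.frame(ctad_id = "T1", stage = "s2",
                     replicate = seq_along(vals_b), d_score = vals_b))
  }
  same <- differential_dscore(mk_tab(c(.2, .2, .2), c(.2, .2, .2)),
                              c("s1", "s2"))
  expect_equal(same$p, 1); expect_false(same$flagged)
  expect_warning(
    deg <- differential_dscore(mk_tab(c(.2, .2), c(.3, .3)), c("s1", "s2")),
    "degenerate")
  expect_true(deg$flagged)
  expect_equal(deg$direction, "increased")

  # planted intra-TAD change 1.5 -> 1.0 detected across seeds
  hits <- 0L
  for (sd in 1:10) {
    cfg <- sim_config(n_bins = 150, compartment_contrast = 0,
                      loop_enrichment = 0, pei_enrichment = 0,
                      tad_enrichment = 1.5, n_replicates = 3,
                      flip_block_stage = NA, drop_boundary_stage = NA,
                      depth = 3e5, seed = 77)
    tr <- build_truth(cfg)
    cfg2 <- cfg; cfg2$tad_enrichment <- 1.0
    Ea <- build_expected_map(tr, cfg, 1)
    Eb <- build_expected_map(tr, cfg2, 1)
    ct <- consensus_tads(list(tr$tad_boundaries[[1]]), n_bins = 150)
    tab <- rbind(
      do.call(rbind, lapply(1:3, function(r) domain_score(
        kr_balance(sample_replicate(Ea, cfg, seed = sd * 100 + r)),
        ct, stage = "a", replicate = r))),
      do.call(rbind, lapply(1:3, function(r) domain_score(
        kr_balance(sample_replicate(Eb, cfg2, seed = sd * 100 + 50 + r)),
        ct, stage = "b", replicate = r))))
    dd <- differential_dscore(tab, c("a", "b"))
    frac_dec <- mean(dd$flagged & dd$direction == "decreased")
    if (frac_dec >= 0.5) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})
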