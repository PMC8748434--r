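# Fixture builders shared across the suite; everything is generated in code.

# symmetric map with constant cells
uniform_map <- function(n = 12, value = 4, resolution = 20000,
                        balanced = FALSE) {
  contact_map(matrix(value, n, n), make_bins("chrT", n, resolution),
              resolution, "chrT", balanced = balanced)
}

# map from an explicit upper-triangle entry list (i, j 1-based)
map_from_entries <- function(n, entries, resolution = 20000,
                             balanced = FALSE) {
  M <- matrix(0, n, n)
  for (e in entries) {
    M[e[1], e[2]] <- e[3]
    M[e[2], e[1]] <- e[3]
  }
  contact_map(M, make_bins("chrT", n, resolution), resolution, "chrT",
              balanced = balanced)
}

# random symmetric positive map
random_map <- function(n = 20, seed = 1, resolution = 20000) {
  set.seed(seed)
  M <- matrix(stats::runif(n * n, 0.5, 5), n, n)
  M <- (M + t(M)) / 2
  contact_map(M, make_bins("chrT", n, resolution), resolution, "chrT")
}

# map giving prescribed DI window sums for the center bin (21 bins, window 10)
di_probe_map <- function(up_total, down_total) {
  M <- matrix(0, 21, 21)
  M[11, 1:10] <- up_total / 10
  M[11, 12:21] <- down_total / 10
  M[1:10, 11] <- up_total / 10
  M[12:21, 11] <- down_total / 10
  M[1, 2] <- M[2, 1] <- 1  # keep total positive even when A = B = 0
  contact_map(M, make_bins("chrT", 21, 20000), 20000, "chrT",
              balanced = TRUE)
}

# small simulated stage-1 map plus its truth
small_sim <- function(n_bins = 300, depth = 6e5, seed = 3, rep_seed = 14, ...) {
  cfg <- sim_config(n_bins = n_bins, depth = depth, seed = seed, ...)
  truth <- build_truth(cfg)
  E <- build_expected_map(truth, cfg, 1)
  map <- sample_replicate(E, cfg, seed = rep_seed)
  list(cfg = cfg, truth = truth, expected = E, map = map,
       balanced = kr_balance(map))
}

# pure power-law decay map (no planted structure)
null_map <- function(n_bins = 400, depth = 8e5, seed = 1, resolution = 5000) {
  cfg <- sim_config(n_bins = n_bins, resolution = resolution,
                    compartment_contrast = 0, tad_enrichment = 0,
                    loop_enrichment = 0, pei_enrichment = 0, depth = depth,
                    flip_block_stage = NA, drop_boundary_stage = NA,
                    seed = seed)
  truth <- build_truth(cfg)
  E <- build_expected_map(truth, cfg, 1)
  list(cfg = cfg, truth = truth,
       balanced = kr_balance(sample_replicate(E, cfg, seed = seed + 1)))
}
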