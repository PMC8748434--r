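#' Configuration for the synthetic contact-map generator
#'
#' The generator emulates the structures a developmental Hi-C study
#' analyzes: power-law distance decay, checkerboard A/B compartments,
#' block-diagonal TAD enrichment, corner loop peaks flanked by convergent
#' CTCF motifs, promoter-anchored enrichment above decay, bimodal H3K27ac
#' signal (broad super-enhancers, moderate regular enhancers, silent poised
#' enhancers), replicate-level Poisson sampling noise, and stage-dependent
#' expression coupled to compartment status and regulatory potential.
#'
#' Stage differences are planted as explicit toggles (flip one compartment
#' block, delete one TAD boundary, stage-restricted loops and
#' promoter-enhancer contacts) so that every downstream "dynamic" call has a
#' known truth.
#'
#' @param n_bins number of bins on the single simulated chromosome.
#' @param resolution bin width (bp); 20 kb for the compartment/TAD layer,
#'   5 kb for the interaction layer.
#' @param decay_exponent power-law exponent `alpha` of the distance decay
#'   `(1 + d)^-alpha`.
#' @param compartment_contrast multiplicative checkerboard contrast `c`:
#'   same-compartment cells x(1+c), cross-compartment x(1-c).
#' @param tad_enrichment intra-TAD enrichment `t` (cells in the same domain
#'   x(1+t)).
#' @param loop_enrichment corner-peak enrichment `l` at loop anchors
#'   (+/- 1 bin).
#' @param pei_enrichment enrichment `p` at planted promoter-enhancer cells.
#' @param depth expected total contact count per replicate.
#' @param n_replicates replicates per stage.
#' @param overdispersion gamma-Poisson overdispersion (0 = pure Poisson).
#' @param stages character vector of stage names (three for switch calling).
#' @param flip_block_stage stage index whose middle compartment block is
#'   flipped (NA = none).
#' @param drop_boundary_stage stage index in which one TAD boundary is
#'   deleted (NA = none).
#' @param n_loops,n_peis counts of planted loops / promoter-enhancer pairs
#'   (scaled down automatically for small maps).
#' @param expr_beta_a,expr_beta_r,expr_sd expression model: log-expression
#'   gains for A-compartment membership and standardized regulatory
#'   potential, and the lognormal noise sd.
#' @param chrom chromosome name.
#' @param seed integer; fixes all randomness of the simulation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_bins = 1000, resolution = 20000,
                       decay_exponent = 1, compartment_contrast = 0.5,
                       tad_enrichment = 1, loop_enrichment = 5,
                       pei_enrichment = 4, depth = 2e6,
                       n_replicates = 2, overdispersion = 0,
                       stages = c("SWF", "F1", "POF"),
                       flip_block_stage = 3L, drop_boundary_stage = 2L,
                       n_loops = 25, n_peis = 80,
                       expr_beta_a = 1, expr_beta_r = 0.5, expr_sd = 0.3,
                       chrom = "chrS", seed = 1L) {
  stopifnot(n_bins >= 20, depth > 0, n_replicates >= 1,
            compartment_contrast >= 0, compartment_contrast < 1,
            tad_enrichment >= 0, loop_enrichment >= 0, pei_enrichment >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# Deterministic local RNG: evaluate expr under a seed without touching the
# caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Plant the ground-truth architecture for a simulation
#'
#' @param cfg a [sim_config()].
#' @return a `truth_set` list: per-stage compartment labels, per-stage TAD
#'   boundary bins (1-based interior domain-start bins), per-stage loops and
#'   promoter-enhancer pairs, CTCF motifs with strand, gene table and
#'   enhancer classes.  Records which block was flipped and which boundary
#'   dropped.
#' @export
build_truth <- function(cfg) with_seed(cfg$seed, {
  n <- cfg$n_bins
  n_stage <- length(cfg$stages)

  ## --- TADs: domain sizes 10-35 bins; boundaries are domain-start bins ---
  tsz <- integer(0)
  while (sum(tsz) < n) tsz <- c(tsz, sample(10:35, 1))
  tsz[length(tsz)] <- tsz[length(tsz)] - (sum(tsz) - n)
  if (tsz[length(tsz)] < 5) {
    tsz <- tsz[-length(tsz)]
    tsz[length(tsz)] <- n - sum(tsz[-length(tsz)])
  }
  base_bound <- cumsum(tsz)[-length(tsz)] + 1L  # interior domain starts
  bounds <- rep(list(base_bound), n_stage)
  names(bounds) <- cfg$stages

  ## --- compartments: alternating blocks of ~30-70 bins assembled from
  ## whole TADs, so every A/B transition coincides with a domain boundary
  ## (as in real genomes, where compartment edges insulate) ---
  tad_start <- c(1L, base_bound)
  tad_end <- c(base_bound - 1L, n)
  sizes <- integer(0)
  k <- 1L
  while (k <= length(tad_start)) {
    tgt <- sample(30:70, 1)
    len <- 0L
    while (k <= length(tad_start) && len < tgt) {
      len <- len + (tad_end[k] - tad_start[k] + 1L)
      k <- k + 1L
    }
    sizes <- c(sizes, len)
  }
  base_lab <- rep(rep(c("A", "B"), length.out = length(sizes)), times = sizes)
  comp <- rep(list(base_lab), n_stage)
  names(comp) <- cfg$stages
  flipped_block <- NULL
  if (!is.na(cfg$flip_block_stage) && length(sizes) >= 3) {
    bi <- ceiling(length(sizes) / 2)
    s0 <- sum(sizes[seq_len(bi - 1)]) + 1L
    s1 <- s0 + sizes[bi] - 1L
    lab <- comp[[cfg$flip_block_stage]]
    lab[s0:s1] <- ifelse(lab[s0:s1] == "A", "B", "A")
    comp[[cfg$flip_block_stage]] <- lab
    flipped_block <- c(start_bin = s0, end_bin = s1)
  }

  ## gene-density orientation track: A blocks are gene-dense (stage-stable)
  gene_density <- stats::rpois(n, ifelse(base_lab == "A", 3, 0.8))
  dropped_boundary <- NULL
  if (!is.na(cfg$drop_boundary_stage) && length(base_bound) >= 3) {
    k <- ceiling(length(base_bound) / 2)
    dropped_boundary <- base_bound[k]
    bounds[[cfg$drop_boundary_stage]] <- base_bound[-k]
  }

  ## --- loops: anchors at TAD boundary bins, 20 kb - 2 Mb apart ---
  min_sep <- max(2L, ceiling(20000 / cfg$resolution))
  max_sep <- max(min_sep + 1L, floor(2e6 / cfg$resolution))
  anchors <- c(1L, base_bound)
  cand <- expand.grid(a = anchors, b = anchors)
  cand <- cand[cand$b - cand$a >= min_sep & cand$b - cand$a <= max_sep, ]
  cand <- cand[cand$a > 3 & cand$b < n - 3, ]
  nl <- min(cfg$n_loops, nrow(cand))
  pick <- cand[sample.int(nrow(cand), nl), ]
  n_specific <- min(floor(nl / 5), 3) # per-stage-specific loops
  loop_stage <- rep(0L, nl)           # 0 = all stages
  if (nl > 3 * n_specific && n_specific > 0)
    loop_stage[seq_len(n_stage * n_specific)] <- rep(seq_len(n_stage), each = n_specific)
  loops <- lapply(seq_len(n_stage), function(s) {
    sel <- loop_stage == 0L | loop_stage == s
    data.frame(bin_i = pick$a[sel], bin_j = pick$b[sel],
               enrichment = cfg$loop_enrichment)
  })
  names(loops) <- cfg$stages

  ## --- CTCF motifs: convergent at loop anchors; tandem + scattered decoys ---
  res <- cfg$resolution
  pos_of <- function(bin) (bin - 1) * res + floor(res / 2)
  ctcf <- data.frame(bin = c(pick$a, pick$b),
                     strand = rep(c("+", "-"), each = nl))
  # tandem (+,+) decoy pairs, kept clear of every other motif so their
  # non-convergence is unambiguous; plus scattered single decoys elsewhere
  away <- function(cand, taken, gap = 3L)
    cand[vapply(cand, function(x) all(abs(taken - x) > gap), logical(1))]
  free <- away(5:(n - 5), c(pick$a, pick$b))
  nd <- 0L
  da <- db <- integer(0)
  for (try in seq_len(200)) {
    if (nd >= 15L || length(free) < 2) break
    cand <- sample(free, 1)
    cand2 <- cand + min_sep + 2L
    if (cand2 %in% free) {
      da <- c(da, cand); db <- c(db, cand2); nd <- nd + 1L
      free <- away(free, c(cand, cand2))
    }
  }
  if (nd > 0) ctcf <- rbind(ctcf, data.frame(bin = c(da, db), strand = "+"))
  if (length(free) > 10) {
    sc <- sample(free, min(30L, floor(length(free) / 3)))
    ctcf <- rbind(ctcf, data.frame(bin = sc, strand = sample(c("+", "-"),
                                                             length(sc), TRUE)))
  }
  ctcf$pos <- pos_of(ctcf$bin)
  decoy_pairs <- if (nd > 0) data.frame(bin_i = da, bin_j = db) else NULL

  ## --- genes and promoter-enhancer pairs ---
  ng <- max(20L, min(120L, floor(n / 8)))
  tss_bins <- sort(sample(5:(n - 5), ng))
  genes <- data.frame(gene = sprintf("g%03d", seq_len(ng)),
                      tss_bin = tss_bins,
                      tss_pos = pos_of(tss_bins),
                      base_expr = exp(stats::rnorm(ng, log(20), 0.8)))
  min_pe <- max(1L, ceiling(15000 / res))
  max_pe <- min(60L, floor(n / 10))
  np <- min(cfg$n_peis, ng * 2L)
  prom_idx <- sample(seq_len(ng), np, replace = TRUE)
  off <- sample(min_pe:max_pe, np, replace = TRUE) * sample(c(-1, 1), np, TRUE)
  ebin <- pmax(3L, pmin(n - 2L, genes$tss_bin[prom_idx] + off))
  keepp <- abs(ebin - genes$tss_bin[prom_idx]) >= min_pe
  prom_idx <- prom_idx[keepp]; ebin <- ebin[keepp]; np <- sum(keepp)
  # stage patterns: 0 = constitutive; s = only in stage s (differential truth)
  pei_stage <- sample(c(0L, seq_len(n_stage)), np, replace = TRUE,
                      prob = c(0.55, rep(0.45 / n_stage, n_stage)))
  pei_all <- data.frame(gene = genes$gene[prom_idx],
                        promoter_bin = genes$tss_bin[prom_idx],
                        enhancer_bin = ebin,
                        enrichment = cfg$pei_enrichment,
                        stage_pattern = pei_stage)
  peis <- lapply(seq_len(n_stage), function(s)
    pei_all[pei_all$stage_pattern %in% c(0L, s), , drop = FALSE])
  names(peis) <- cfg$stages

  ## --- enhancer classes for the planted enhancer bins ---
  ## only bins >= 4 bins apart get a class, so stitched H3K27ac regions from
  ## different enhancers cannot merge and blur the planted classes
  ubins <- sort(unique(pei_all$enhancer_bin))
  keep_sp <- logical(length(ubins)); last <- -10L
  for (k in seq_along(ubins)) {
    if (ubins[k] - last >= 4L) { keep_sp[k] <- TRUE; last <- ubins[k] }
  }
  ubins <- ubins[keep_sp]
  cls <- sample(c("SE", "RE", "PE"), length(ubins), replace = TRUE,
                prob = c(0.25, 0.5, 0.25))
  enh <- data.frame(enhancer_bin = ubins, class = cls)

  structure(list(
    compartment_labels = comp, gene_density = gene_density,
    tad_boundaries = bounds,
    loops = loops, ctcf_motifs = ctcf, decoy_pairs = decoy_pairs,
    peis = peis, pei_all = pei_all, genes = genes,
    enhancer_classes = enh,
    flipped_block = flipped_block, dropped_boundary = dropped_boundary,
    cfg = cfg), class = "truth_set")
})

#' Noise-free expected contact matrix for one stage
#'
#' `expected[i, j] = (1 + |i-j|)^-alpha x (1 +/- c) x (1 + t) x (1 + l) x
#' (1 + p)` with each factor applied where the corresponding planted feature
#' holds (same compartment, same TAD, loop anchor corner +/- 1 bin, planted
#' promoter-enhancer cell).
#'
#' @param truth a [build_truth()] result.
#' @param cfg the matching [sim_config()].
#' @param stage stage name or index.
#' @return dense symmetric positive matrix.
#' @export
build_expected_map <- function(truth, cfg, stage) {
  n <- cfg$n_bins
  if (is.numeric(stage)) stage <- cfg$stages[stage]
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- (1 + d)^(-cfg$decay_exponent)
  lab <- truth$compartment_labels[[stage]]
  same <- outer(lab, lab, "==")
  E <- E * ifelse(same, 1 + cfg$compartment_contrast, 1 - cfg$compartment_contrast)
  bnd <- truth$tad_boundaries[[stage]]
  tad_id <- findInterval(seq_len(n), c(1L, bnd))
  E <- E * ifelse(outer(tad_id, tad_id, "=="), 1 + cfg$tad_enrichment, 1)
  lp <- truth$loops[[stage]]
  if (!is.null(lp) && nrow(lp) > 0) {
    for (k in seq_len(nrow(lp))) {
      ii <- pmax(1L, lp$bin_i[k] - 1L):pmin(n, lp$bin_i[k] + 1L)
      jj <- pmax(1L, lp$bin_j[k] - 1L):pmin(n, lp$bin_j[k] + 1L)
      E[ii, jj] <- E[ii, jj] * (1 + lp$enrichment[k])
      E[jj, ii] <- E[jj, ii] * (1 + lp$enrichment[k])
    }
  }
  pe <- truth$peis[[stage]]
  if (!is.null(pe) && nrow(pe) > 0) {
    for (k in seq_len(nrow(pe))) {
      i <- pe$promoter_bin[k]; j <- pe$enhancer_bin[k]
      E[i, j] <- E[i, j] * (1 + pe$enrichment[k])
      E[j, i] <- E[i, j]
    }
  }
  E
}

#' Sample one sequencing replicate from an expected matrix
#'
#' Upper-triangle cells are drawn independently from a Poisson (or, with
#' `overdispersion > 0`, gamma-Poisson) distribution with mean proportional
#' to the expected matrix, scaled so the total count is approximately
#' `depth`; the lower triangle is mirrored.
#'
#' @param expected dense symmetric positive matrix.
#' @param cfg a [sim_config()] supplying bins/chrom/overdispersion.
#' @param depth target total contact count.
#' @param seed integer seed; same seed, same map.
#' @return a raw [contact_map].
#' @export
sample_replicate <- function(expected, cfg, depth = cfg$depth, seed = cfg$seed) {
  n <- nrow(expected)
  ut <- upper.tri(expected, diag = TRUE)
  lam <- expected[ut] * (depth / sum(expected[ut]))
  cnt <- with_seed(seed, {
    if (cfg$overdispersion > 0) {
      size <- 1 / cfg$overdispersion
      stats::rnbinom(length(lam), mu = lam, size = size)
    } else stats::rpois(length(lam), lam)
  })
  M <- matrix(0, n, n)
  M[ut] <- cnt
  M <- M + t(M) - diag(diag(M))
  contact_map(M, make_bins(cfg$chrom, n, cfg$resolution), cfg$resolution,
              cfg$chrom)
}

#' Per-gene/stage regulatory-potential ground truth
#'
#' Sum of planted enrichments over the gene's stage-present
#' promoter-enhancer pairs; the simulation's analogue of the regulatory
#' potential score.
#'
#' @param truth a `truth_set`.
#' @return data.frame gene x stage x rps_truth.
#' @export
rps_truth <- function(truth) {
  cfg <- truth$cfg
  out <- expand.grid(gene = truth$genes$gene, stage = cfg$stages,
                     stringsAsFactors = FALSE)
  out$rps_truth <- mapply(function(g, s) {
    pe <- truth$peis[[s]]
    sum(log10(1 + pe$enrichment[pe$gene == g]))
  }, out$gene, out$stage)
  out
}

#' Simulate companion annotation and expression tracks
#'
#' Gene expression per stage and replicate follows
#' `base x exp(beta_A [in A] + beta_R z(RPS_truth) + noise)`; H3K27ac peaks
#' are broad and strong over SE enhancers (>= 5 stitchable member peaks),
#' single and moderate over REs, absent over PEs; CTCF motifs are convergent
#' at planted loop anchors with tandem and scattered decoys elsewhere.
#'
#' @param truth a `truth_set`.
#' @param cfg the matching [sim_config()].
#' @param seed integer seed.
#' @param compartment_of optional function(bin) -> "A"/"B" per stage (list
#'   over stages); defaults to the truth's own per-stage labels at the TSS.
#' @return list with `expression` (gene, stage, replicate, tpm),
#'   `h3k27ac` (chrom, start, end, signal), `ctcf` (BED6-style data.frame).
#' @export
simulate_tracks <- function(truth, cfg, seed = cfg$seed + 1000L,
                            compartment_of = NULL) with_seed(seed, {
  genes <- truth$genes
  rt <- rps_truth(truth)
  res <- cfg$resolution
  expr <- do.call(rbind, lapply(seq_along(cfg$stages), function(si) {
    s <- cfg$stages[si]
    lab <- if (is.null(compartment_of)) truth$compartment_labels[[s]][genes$tss_bin]
           else compartment_of[[s]](genes$tss_bin)
    r <- rt$rps_truth[rt$stage == s][match(genes$gene, rt$gene[rt$stage == s])]
    z <- if (stats::sd(r) > 0) (r - mean(r)) / stats::sd(r) else r * 0
    do.call(rbind, lapply(seq_len(cfg$n_replicates), function(rep) {
      data.frame(gene = genes$gene, stage = s, replicate = rep,
                 tpm = genes$base_expr *
                   exp(cfg$expr_beta_a * (lab == "A") + cfg$expr_beta_r * z +
                       stats::rnorm(nrow(genes), 0, cfg$expr_sd)))
    }))
  }))

  ## H3K27ac peaks: SE = 5-7 member peaks within 12.5 kb gaps, high signal;
  ## RE = one moderate peak; PE = nothing.
  peaks <- list()
  for (k in seq_len(nrow(truth$enhancer_classes))) {
    e <- truth$enhancer_classes[k, ]
    center <- (e$enhancer_bin - 1) * res + floor(res / 2)
    if (e$class == "SE") {
      m <- sample(5:7, 1)
      st <- center + cumsum(c(0, sample(2000:4000, m - 1, TRUE)))
      peaks[[length(peaks) + 1]] <- data.frame(
        chrom = cfg$chrom, start = st, end = st + 1500,
        signal = stats::rnorm(m, 60, 8), class = "SE",
        enhancer_bin = e$enhancer_bin)
    } else if (e$class == "RE") {
      peaks[[length(peaks) + 1]] <- data.frame(
        chrom = cfg$chrom, start = center, end = center + 1500,
        signal = stats::rnorm(1, 8, 1.5), class = "RE",
        enhancer_bin = e$enhancer_bin)
    }
  }
  h3k27ac <- if (length(peaks)) do.call(rbind, peaks)
             else data.frame(chrom = character(), start = numeric(),
                             end = numeric(), signal = numeric(),
                             class = character(), enhancer_bin = integer())
  h3k27ac$signal <- pmax(h3k27ac$signal, 1)

  ctcf <- data.frame(chrom = cfg$chrom, start = truth$ctcf_motifs$pos,
                     end = truth$ctcf_motifs$pos + 19,
                     name = "CTCF", score = 0,
                     strand = truth$ctcf_motifs$strand)
  list(expression = expr, h3k27ac = h3k27ac, ctcf = ctcf)
})

#' Simulate a full three-stage, two-layer study
#'
#' Builds a coarse (compartment/TAD) layer with per-stage replicate maps and
#' a fine (promoter-enhancer/loop) layer with pooled per-stage maps over the
#' first part of the same chromosome, plus expression and annotation tracks.
#'
#' @param coarse a [sim_config()] for the 20 kb layer (compartments + TADs).
#' @param fine a [sim_config()] for the 5 kb layer (PEIs + loops); defaults
#'   to a 1,000-bin 5 kb config derived from `coarse`'s seed.
#' @return list with `coarse_truth`, `fine_truth`, `coarse_maps`
#'   (stage -> list of replicate [contact_map]s), `fine_maps` (stage ->
#'   pooled [contact_map]), and `tracks`.
#' @export
simulate_study <- function(coarse = sim_config(), fine = NULL) {
  if (is.null(fine))
    fine <- sim_config(n_bins = 1000, resolution = 5000,
                       compartment_contrast = 0, tad_enrichment = 1,
                       loop_enrichment = coarse$loop_enrichment,
                       pei_enrichment = coarse$pei_enrichment,
                       depth = coarse$depth, n_replicates = coarse$n_replicates,
                       stages = coarse$stages, flip_block_stage = NA,
                       drop_boundary_stage = NA, chrom = coarse$chrom,
                       seed = coarse$seed + 7L)
  ct <- build_truth(coarse)
  ft <- build_truth(fine)
  n_stage <- length(coarse$stages)
  coarse_maps <- lapply(seq_len(n_stage), function(s) {
    E <- build_expected_map(ct, coarse, s)
    lapply(seq_len(coarse$n_replicates), function(r)
      sample_replicate(E, coarse, seed = coarse$seed + 100L * s + r))
  })
  names(coarse_maps) <- coarse$stages
  fine_maps <- lapply(seq_len(n_stage), function(s) {
    E <- build_expected_map(ft, fine, s)
    reps <- lapply(seq_len(fine$n_replicates), function(r)
      sample_replicate(E, fine, seed = fine$seed + 100L * s + r))
    pooled <- Reduce(`+`, lapply(reps, function(m) m$mat))
    contact_map(pooled, reps[[1]]$bins, fine$resolution, fine$chrom)
  })
  names(fine_maps) <- fine$stages
  # genes live on the fine layer; compartment status read off the coarse truth
  comp_of <- lapply(coarse$stages, function(s) {
    lab <- ct$compartment_labels[[s]]
    function(bin_fine) {
      bp <- (bin_fine - 1) * fine$resolution
      lab[pmin(length(lab), floor(bp / coarse$resolution) + 1L)]
    }
  })
  names(comp_of) <- coarse$stages
  tracks <- simulate_tracks(ft, fine, compartment_of = comp_of)
  list(coarse_truth = ct, fine_truth = ft, coarse_maps = coarse_maps,
       fine_maps = fine_maps, tracks = tracks,
       coarse_cfg = coarse, fine_cfg = fine)
}
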