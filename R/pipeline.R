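#' Configuration for the full three-stage analysis
#'
#' Collects every module threshold at its standard default: PEI FDR 0.01
#' and minimum distance 15 kb, loop q 0.05 in 20 kb - 2 Mb with a
#' top-15,000 cap, A-TAD fraction 0.7, consensus boundary fraction 0.5,
#' differential domain-score alpha 0.05, differential-RPS cutoffs
#' |log2FC| > 1.5 and |dRPS| > 3, H3K27ac stitch 12.5 kb, 1,000
#' permutations for specific boundaries, boundary tolerance 1 bin.
#'
#' @param coarse,fine simulation configs ([sim_config()]) for the 20 kb
#'   (compartment/TAD) and 5 kb (PEI/loop) layers; `fine = NULL` derives a
#'   default from `coarse`.
#' @param pei_fdr,pei_min_dist,loop_q,loop_min_d,loop_max_d,loop_top_k
#'   interaction thresholds.
#' @param atad_frac,consensus_frac,dscore_alpha,boundary_tol,n_perm TAD
#'   thresholds.
#' @param rps_fc_cut,rps_delta_cut,stitch RPS and enhancer thresholds.
#' @param rps_k,expr_k k-means cluster counts for RPS and expression
#'   profiles.
#' @param seed global seed; all randomness derives from it.
#' @param outdir optional directory for artifact tables (NULL = no files).
#' @return a `run_config` list.
#' @export
run_config <- function(coarse = sim_config(), fine = NULL,
                       pei_fdr = 0.01, pei_min_dist = 15000,
                       loop_q = 0.05, loop_min_d = 20000, loop_max_d = 2e6,
                       loop_top_k = 15000,
                       atad_frac = 0.7, consensus_frac = 0.5,
                       dscore_alpha = 0.05, boundary_tol = 1, n_perm = 1000,
                       rps_fc_cut = 1.5, rps_delta_cut = 3, stitch = 12500,
                       rps_k = 6, expr_k = 4,
                       seed = 1L, outdir = NULL) {
  coarse$seed <- as.integer(seed)
  if (!is.null(fine)) fine$seed <- as.integer(seed) + 7L
  structure(as.list(environment()), class = "run_config")
}

#' Run the full three-stage chromatin-architecture analysis
#'
#' Simulates (or accepts) the study, then per stage: balances maps,
#' computes Von Neumann entropy per replicate, calls compartments on the
#' pooled map, calls TADs per replicate and on the pooled map; across
#' stages: classifies compartment switches, measures boundary overlap and
#' stage-specific boundaries, builds consensus TADs with domain scores and
#' differential tests; on the fine layer: calls promoter-enhancer
#' interactions, regulatory potential scores with differential analysis
#' and profile clustering, enhancer classes, loops and CTCF convergence,
#' and the promoter-skipping fraction.  Deterministic given the config.
#'
#' @param config a [run_config()].
#' @param study optional pre-built [simulate_study()] result (it must match
#'   `config`); simulated from the config when NULL.
#' @return a `stage_report` list; see elements `vne`, `compartments`,
#'   `switches`, `tads`, `boundary_dynamics`, `consensus`, `dscore`,
#'   `peis`, `rps`, `loops`, `enhancers`, `summary`.
#' @export
run_pipeline <- function(config, study = NULL) {
  if (is.null(study)) study <- simulate_study(config$coarse, config$fine)
  stages <- config$coarse$stages
  if (length(stages) != 3)
    stop("switch classification requires exactly three stages")
  ct <- study$coarse_truth

  ## ---- coarse layer: balance, VNE, compartments, TADs ----
  bal_rep <- lapply(stages, function(s)
    lapply(study$coarse_maps[[s]], kr_balance))
  names(bal_rep) <- stages
  bal_pool <- lapply(stages, function(s) {
    pooled <- Reduce(`+`, lapply(study$coarse_maps[[s]], function(m) m$mat))
    kr_balance(contact_map(pooled, study$coarse_maps[[s]][[1]]$bins,
                           config$coarse$resolution, config$coarse$chrom))
  })
  names(bal_pool) <- stages

  vne <- do.call(rbind, lapply(stages, function(s)
    do.call(rbind, lapply(seq_along(bal_rep[[s]]), function(r)
      von_neumann_entropy(bal_rep[[s]][[r]], stage = s, replicate = r)))))

  profiles <- lapply(stages, function(s)
    compute_pc1(bal_pool[[s]], ct$gene_density, stage = s))
  names(profiles) <- stages
  switches <- classify_switches(profiles, bal_pool[[1]]$bins)

  tads_rep <- lapply(stages, function(s)
    lapply(bal_rep[[s]], call_tads, seed = config$seed))
  names(tads_rep) <- stages
  tads_stage <- lapply(stages, function(s) call_tads(bal_pool[[s]], seed = config$seed))
  names(tads_stage) <- stages
  di_stage <- lapply(bal_pool, directionality_index)

  boundary_dynamics <- lapply(1:2, function(k) {
    a <- stages[k]; b <- stages[k + 1]
    ov <- boundary_overlap(tads_stage[[a]], tads_stage[[b]], config$boundary_tol)
    cand <- sort(unique(c(ov$specific_a, ov$specific_b)))
    spec <- specific_boundary_test(di_stage[[a]], di_stage[[b]], cand,
                                   n_perm = config$n_perm,
                                   seed = config$seed + 31L * k)
    list(pair = c(a, b), overlap = ov, specific = spec)
  })
  names(boundary_dynamics) <- paste(stages[1:2], stages[2:3], sep = "_vs_")

  all_sets <- unlist(tads_rep, recursive = FALSE)
  consensus <- consensus_tads(all_sets, config$consensus_frac,
                              config$boundary_tol,
                              n_bins = config$coarse$n_bins)
  consensus$domains$compartment_class <- vapply(
    seq_len(nrow(consensus$domains)), function(k)
      classify_tad_compartment(consensus$domains[k, ], profiles[[1]],
                               config$atad_frac), character(1))
  dtab <- do.call(rbind, lapply(stages, function(s)
    do.call(rbind, lapply(seq_along(bal_rep[[s]]), function(r)
      domain_score(bal_rep[[s]][[r]], consensus, stage = s, replicate = r)))))
  ddiff <- lapply(1:2, function(k)
    differential_dscore(dtab, stages[k:(k + 1)], config$dscore_alpha))
  names(ddiff) <- names(boundary_dynamics)

  ## ---- fine layer: PEIs, RPS, loops, enhancers ----
  ftruth <- study$fine_truth
  fbal <- lapply(stages, function(s) kr_balance(study$fine_maps[[s]]))
  names(fbal) <- stages
  gene_map <- ftruth$genes[, c("gene", "tss_bin")]
  names(gene_map)[2] <- "promoter_bin"
  peis <- lapply(stages, function(s)
    call_peis(fbal[[s]], ftruth$genes$tss_bin, fdr = config$pei_fdr,
              min_dist = config$pei_min_dist))
  names(peis) <- stages
  rps <- lapply(stages, function(s) compute_rps(peis[[s]], gene_map, stage = s))
  names(rps) <- stages
  rps_diff <- lapply(1:2, function(k)
    differential_rps(rps[[stages[k]]], rps[[stages[k + 1]]],
                     config$rps_fc_cut, config$rps_delta_cut))
  names(rps_diff) <- names(boundary_dynamics)

  rps_mat <- sapply(stages, function(s) rps[[s]]$rps)
  rownames(rps_mat) <- rps[[1]]$gene
  dyn_genes <- unique(c(rps_diff[[1]]$gene[rps_diff[[1]]$flagged],
                        rps_diff[[2]]$gene[rps_diff[[2]]$flagged]))
  rps_clusters <- if (length(dyn_genes) >= 2 * config$rps_k)
    tryCatch(cluster_profiles(rps_mat[dyn_genes, , drop = FALSE],
                              config$rps_k, seed = config$seed),
             error = function(e) NULL) else NULL

  expr <- study$tracks$expression
  expr_mat <- sapply(stages, function(s) {
    e <- expr[expr$stage == s, ]
    tapply(e$tpm, e$gene, mean)[ftruth$genes$gene]
  })
  rownames(expr_mat) <- ftruth$genes$gene
  expr_clusters <- cluster_profiles(log2(expr_mat + 1), config$expr_k,
                                    seed = config$seed)

  res_f <- config$coarse$resolution  # genes annotated on coarse grid too
  loops <- lapply(stages, function(s)
    convergent_filter(
      call_loops(fbal[[s]], config$loop_min_d, config$loop_max_d,
                 config$loop_q, config$loop_top_k),
      data.frame(bin = ftruth$ctcf_motifs$bin,
                 strand = ftruth$ctcf_motifs$strand)))
  names(loops) <- stages

  fres <- config$coarse$resolution
  pei_regions <- {
    eb <- sort(unique(unlist(lapply(peis, function(p) p$enhancer_bin))))
    r <- study$fine_cfg$resolution
    data.frame(chrom = study$fine_cfg$chrom, start = (eb - 1) * r,
               end = eb * r, enhancer_bin = eb)
  }
  enhancers <- classify_enhancers(study$tracks$h3k27ac, config$stitch,
                                  pei_regions)
  skip_frac <- promoter_skip_fraction(peis[[2]], ftruth$genes$tss_bin)

  ## ---- expression comparisons (rank-sum) ----
  s1 <- stages[1]
  lab1 <- profiles[[s1]]$label
  gbin_coarse <- floor(ftruth$genes$tss_pos / config$coarse$resolution) + 1L
  glab <- lab1[gbin_coarse]
  e1 <- expr_mat[, s1]
  ab_test <- if (sum(glab == "A") >= 2 && sum(glab == "B") >= 2)
    compare_groups_expression(e1[glab == "A"], e1[glab == "B"]) else NULL

  summary <- list(
    vne_by_stage = tapply(vne$vne, vne$stage, mean)[stages],
    switched_fraction = switches$switched_fraction,
    n_boundaries = vapply(tads_stage, function(t) length(t$boundaries), numeric(1)),
    n_ctads = nrow(consensus$domains),
    median_tad_kb = stats::median(
      (consensus$domains$end_bin - consensus$domains$start_bin + 1) *
        config$coarse$resolution / 1000),
    n_peis = vapply(peis, nrow, numeric(1)),
    n_loops = vapply(loops, nrow, numeric(1)),
    n_convergent = vapply(loops, function(l)
      sum(l$ctcf_orientation == "convergent"), numeric(1)),
    skip_fraction = skip_frac,
    n_diff_rps = vapply(rps_diff, function(d) sum(d$flagged), numeric(1)),
    ab_expression_p = if (!is.null(ab_test)) ab_test$p else NA)

  out <- list(config = config, study = study, vne = vne,
              compartments = profiles, switches = switches,
              tads_rep = tads_rep, tads_stage = tads_stage,
              boundary_dynamics = boundary_dynamics,
              consensus = consensus, dscore = dtab, dscore_diff = ddiff,
              peis = peis, rps = rps, rps_diff = rps_diff,
              rps_clusters = rps_clusters, expr_clusters = expr_clusters,
              loops = loops, enhancers = enhancers,
              skip_fraction = skip_frac, summary = summary)
  class(out) <- "stage_report"
  if (!is.null(config$outdir)) write_report(out, config$outdir)
  out
}

#' @export
print.stage_report <- function(x, ...) {
  s <- x$summary
  cat("Three-stage chromatin architecture report\n")
  cat("  VNE:", paste(sprintf("%s=%.3f", names(s$vne_by_stage),
                              s$vne_by_stage), collapse = " "), "\n")
  cat(sprintf("  switched fraction: %.3f\n", s$switched_fraction))
  cat(sprintf("  consensus TADs: %d (median %.0f kb)\n",
              s$n_ctads, s$median_tad_kb))
  cat("  PEIs:", paste(s$n_peis, collapse = "/"),
      " loops:", paste(s$n_loops, collapse = "/"), "\n")
  invisible(x)
}

#' Write report tables to a directory
#'
#' Emits TSV/BED-style text artifacts: per-bin PC1 bedGraph per stage,
#' switch segments, boundaries, consensus domains with compartment class,
#' domain scores, differential domain scores, PEIs, RPS, differential RPS,
#' loops with CTCF orientation, enhancer classes, and the summary.
#'
#' @param report a `stage_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  bins <- report$study$coarse_maps[[1]][[1]]$bins
  for (s in names(report$compartments)) {
    p <- report$compartments[[s]]
    wt(data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                  pc1 = p$pc1, label = p$label),
       paste0("pc1_", s, ".bedgraph.tsv"))
  }
  wt(report$switches$segments, "switch_segments.tsv")
  wt(report$vne, "vne.tsv")
  wt(report$consensus$domains, "consensus_tads.tsv")
  wt(report$dscore, "domain_scores.tsv")
  for (nm in names(report$dscore_diff))
    wt(report$dscore_diff[[nm]], paste0("dscore_diff_", nm, ".tsv"))
  for (s in names(report$peis)) wt(report$peis[[s]], paste0("peis_", s, ".tsv"))
  for (s in names(report$rps)) wt(report$rps[[s]], paste0("rps_", s, ".tsv"))
  for (s in names(report$loops)) wt(report$loops[[s]], paste0("loops_", s, ".tsv"))
  wt(report$enhancers, "enhancer_classes.tsv")
  su <- report$summary
  wt(data.frame(key = names(unlist(su)), value = unlist(su)), "summary.tsv")
  invisible(dir)
}

# boundary precision/recall/F1 at a bin tolerance
boundary_f1 <- function(called, truth, tol = 1) {
  called <- sort(unique(as.integer(called)))
  truth <- sort(unique(as.integer(truth)))
  if (!length(called) || !length(truth))
    return(c(precision = 0, recall = 0, f1 = 0))
  prec <- mean(vapply(called, function(x) any(abs(truth - x) <= tol), logical(1)))
  rec <- mean(vapply(truth, function(x) any(abs(called - x) <= tol), logical(1)))
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  c(precision = prec, recall = rec, f1 = f1)
}

#' Planted-truth recovery evaluation
#'
#' Scores every recovery property of a pipeline run against the simulation
#' truth: compartment label accuracy per stage, switched-block detection,
#' TAD-boundary F1 per stage and replicate, detection of the planted
#' boundary loss, PEI and loop recall, convergence-filter exactness on
#' planted and decoy anchors, enhancer class accuracy, and the
#' promoter-skipping estimate versus its planted rate.
#'
#' @param report a `stage_report` from [run_pipeline()].
#' @return list of named metrics plus a `checks` data.frame of pass/fail
#'   verdicts.
#' @export
recovery_report <- function(report) {
  study <- report$study
  ct <- study$coarse_truth
  ft <- study$fine_truth
  stages <- report$config$coarse$stages
  tol <- report$config$boundary_tol

  comp_acc <- vapply(stages, function(s) {
    p <- report$compartments[[s]]
    ok <- p$label != "masked"
    mean(p$label[ok] == ct$compartment_labels[[s]][ok])
  }, numeric(1))

  # planted switch: flipped block should be found among switched segments
  seg <- report$switches$segments
  fb <- ct$flipped_block
  flip_recovered_bp <- if (!is.null(fb)) {
    sw <- seg[seg$class != "stable", , drop = FALSE]
    sum(pmax(0, pmin(sw$end_bin, fb["end_bin"]) -
               pmax(sw$start_bin, fb["start_bin"]) + 1))
  } else NA
  flip_len <- if (!is.null(fb)) fb["end_bin"] - fb["start_bin"] + 1 else NA

  bf1 <- do.call(rbind, lapply(stages, function(s)
    do.call(rbind, lapply(seq_along(report$tads_rep[[s]]), function(r) {
      f <- boundary_f1(report$tads_rep[[s]][[r]]$boundaries,
                       ct$tad_boundaries[[s]], tol)
      data.frame(stage = s, replicate = r, t(f))
    }))))

  # planted boundary loss: dropped boundary called in flanking stages but
  # not the drop stage
  ds <- report$config$coarse$drop_boundary_stage
  loss_detected <- if (!is.null(ct$dropped_boundary) && !is.na(ds)) {
    b <- ct$dropped_boundary
    in_stage <- vapply(stages, function(s)
      any(abs(report$tads_stage[[s]]$boundaries - b) <= tol), logical(1))
    !in_stage[ds] && any(in_stage[-ds])
  } else NA

  pei_recall <- vapply(stages, function(s) {
    planted <- ft$peis[[s]]
    called <- report$peis[[s]]
    if (!nrow(planted)) return(NA_real_)
    mean(vapply(seq_len(nrow(planted)), function(k)
      any(called$promoter_bin == planted$promoter_bin[k] &
            abs(called$enhancer_bin - planted$enhancer_bin[k]) <= 1),
      logical(1)))
  }, numeric(1))

  loop_recall <- vapply(stages, function(s) {
    planted <- ft$loops[[s]]
    called <- report$loops[[s]]
    if (!nrow(planted)) return(NA_real_)
    mean(vapply(seq_len(nrow(planted)), function(k)
      any(abs(called$anchor_i - planted$bin_i[k]) <= 1 &
            abs(called$anchor_j - planted$bin_j[k]) <= 1),
      logical(1)))
  }, numeric(1))

  # convergence filter exactness on planted anchors and tandem decoys
  conv_ok <- {
    lp <- ft$loops[[2]]
    ann <- convergent_filter(
      data.frame(anchor_i = lp$bin_i, anchor_j = lp$bin_j),
      data.frame(bin = ft$ctcf_motifs$bin, strand = ft$ctcf_motifs$strand))
    planted_pass <- all(ann$ctcf_orientation == "convergent")
    decoy_fail <- if (!is.null(ft$decoy_pairs)) {
      dec <- convergent_filter(
        data.frame(anchor_i = ft$decoy_pairs$bin_i,
                   anchor_j = ft$decoy_pairs$bin_j),
        data.frame(bin = ft$ctcf_motifs$bin, strand = ft$ctcf_motifs$strand))
      all(dec$ctcf_orientation != "convergent")
    } else TRUE
    planted_pass && decoy_fail
  }

  # enhancer classes: match stitched/PE regions to planted enhancer bins
  enh_acc <- {
    res <- study$fine_cfg$resolution
    truth_e <- ft$enhancer_classes
    pred <- report$enhancers
    hit <- vapply(seq_len(nrow(truth_e)), function(k) {
      c0 <- (truth_e$enhancer_bin[k] - 1) * res
      c1 <- truth_e$enhancer_bin[k] * res
      ov <- pred$start < c1 + 2000 & pred$end > c0 - 2000
      if (!any(ov)) return(NA)
      any(pred$class[ov] == truth_e$class[k])
    }, logical(1))
    mean(hit, na.rm = TRUE)
  }

  planted_skip <- {
    proms <- ft$genes$tss_bin
    ub <- unique(ft$pei_all$enhancer_bin)
    mean(vapply(ub, function(e) {
      dmin <- min(abs(proms - e))
      partners <- ft$pei_all$promoter_bin[ft$pei_all$enhancer_bin == e]
      !any(abs(partners - e) == dmin)
    }, logical(1)))
  }

  checks <- data.frame(
    property = c("compartment_accuracy_min", "boundary_f1_min",
                 "boundary_loss_detected", "pei_recall_min",
                 "loop_recall_min", "convergence_filter_exact",
                 "flip_block_recovered"),
    value = c(min(comp_acc), min(bf1$f1),
              as.numeric(isTRUE(loss_detected)), min(pei_recall, na.rm = TRUE),
              min(loop_recall, na.rm = TRUE), as.numeric(conv_ok),
              if (!is.na(flip_len)) flip_recovered_bp / flip_len else NA),
    threshold = c(0.95, 0.8, 1, 0.9, 0.9, 1, 0.8))
  checks$pass <- !is.na(checks$value) & checks$value >= checks$threshold

  list(compartment_accuracy = comp_acc,
       flip_recovered_fraction = if (!is.na(flip_len))
         flip_recovered_bp / flip_len else NA,
       boundary_f1 = bf1, boundary_loss_detected = loss_detected,
       pei_recall = pei_recall, loop_recall = loop_recall,
       convergence_filter_exact = conv_ok,
       enhancer_class_accuracy = enh_acc,
       skip_fraction_called = report$skip_fraction,
       skip_fraction_planted = planted_skip,
       checks = checks)
}
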