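## Poisson upper tail P(X >= obs) via the gamma identity; exact for integer
## obs, a smooth interpolation for balanced (non-integer) counts.
pois_upper_tail <- function(obs, lambda) {
  p <- rep(1, length(obs))
  pos <- obs > 0
  p[pos] <- stats::pgamma(lambda[pos], shape = obs[pos], rate = 1)
  p
}

# per-diagonal means of a submatrix over kept bins
diag_means <- function(M, keep) {
  n <- nrow(M)
  idx <- logical(n); idx[keep] <- TRUE
  vapply(0:(n - 1), function(d) {
    i <- seq_len(n - d); j <- i + d
    ok <- idx[i] & idx[j]
    if (any(ok)) mean(M[cbind(i[ok], j[ok])]) else 0
  }, numeric(1))
}

# spline-smoothed distance decay in log-log space; returns a function of
# distance (bins) clipped to the observed range
smooth_decay <- function(expected) {
  d <- seq_along(expected) - 1
  ok <- d >= 1 & expected > 0
  if (sum(ok) < 8) {
    e <- expected
    return(function(dist) e[pmin(pmax(dist, 0), length(e) - 1) + 1])
  }
  fit <- stats::smooth.spline(log(d[ok]), log(expected[ok]), spar = 0.7)
  rng <- range(d[ok])
  function(dist) {
    dist <- pmin(pmax(dist, rng[1]), rng[2])
    exp(stats::predict(fit, log(dist))$y)
  }
}

#' Promoter-enhancer interaction calling
#'
#' Scans the balanced high-resolution map in overlapping windows (default
#' 20 Mb with 10 Mb steps).  Within each window, each promoter bin is
#' tested against every candidate bin at `>= min_dist`: the expectation is
#' the window's spline-smoothed distance decay and the p-value the Poisson
#' upper tail at that mean.  Benjamini-Hochberg correction is applied over
#' all promoter-candidate tests of the map; calls with `q < fdr` are kept,
#' deduplicated across overlapping windows by best q.  Interaction
#' intensity is `log10(observed - expected)`, floored at 0 when
#' `observed - expected <= 1`.
#'
#' @param map a balanced [contact_map] (5 kb resolution in the standard
#'   workflow).
#' @param promoters integer promoter (TSS) bins, 1-based.
#' @param fdr q-value cutoff (default 0.01).
#' @param min_dist minimum interaction distance in bp (default 15000).
#' @param window,step sliding-window size and step in bp.
#' @return data.frame of PEIs: `promoter_bin`, `enhancer_bin`, `distance`
#'   (bp), `observed`, `expected`, `intensity`, `q`.  The total number of
#'   tests is attached as attribute `"n_tests"`.
#' @export
call_peis <- function(map, promoters, fdr = 0.01, min_dist = 15000,
                      window = 20e6, step = 10e6) {
  if (!map$balanced) stop("map must be balanced")
  if (length(promoters) == 0) stop("promoter list is empty")
  M <- map$mat
  n <- nrow(M)
  res <- map$resolution
  min_bins <- ceiling(min_dist / res)
  wb <- max(2 * min_bins + 1, min(n, round(window / res)))
  sb <- max(1, round(step / res))
  starts <- unique(pmin(seq(1L, max(1L, n - wb + 1L), by = sb), n - wb + 1L))
  masked_prom <- promoters[map$mask[promoters]]
  if (length(masked_prom))
    warning("skipping ", length(masked_prom), " masked promoter bin(s)")
  promoters <- setdiff(promoters, masked_prom)
  tests <- list()
  for (w0 in starts) {
    w1 <- min(n, w0 + wb - 1L)
    sub <- M[w0:w1, w0:w1, drop = FALSE]
    keep <- which(!map$mask[w0:w1])
    dec <- smooth_decay(diag_means(sub, keep))
    for (p in promoters[promoters >= w0 & promoters <= w1]) {
      j <- setdiff(which(!map$mask[w0:w1]) + w0 - 1L, p)
      j <- j[abs(j - p) >= min_bins]
      if (!length(j)) next
      lam <- dec(abs(j - p))
      tests[[length(tests) + 1]] <- data.frame(
        promoter_bin = p, enhancer_bin = j,
        observed = M[p, j], expected = lam,
        pval = pois_upper_tail(M[p, j], lam))
    }
  }
  if (!length(tests)) {
    out <- data.frame(promoter_bin = integer(), enhancer_bin = integer(),
                      distance = numeric(), observed = numeric(),
                      expected = numeric(), intensity = numeric(),
                      q = numeric())
    attr(out, "n_tests") <- 0L
    return(out)
  }
  tt <- do.call(rbind, tests)
  tt$q <- stats::p.adjust(tt$pval, method = "BH")
  # dedupe across overlapping windows: best q per (promoter, enhancer)
  key <- paste(tt$promoter_bin, tt$enhancer_bin)
  tt <- tt[order(tt$q), ]
  tt <- tt[!duplicated(paste(tt$promoter_bin, tt$enhancer_bin)), ]
  n_tests <- length(unique(key))
  hit <- tt$q < fdr & tt$observed > tt$expected
  out <- tt[hit, c("promoter_bin", "enhancer_bin", "observed", "expected", "q")]
  out$distance <- abs(out$enhancer_bin - out$promoter_bin) * res
  out$intensity <- ifelse(out$observed - out$expected > 1,
                          log10(out$observed - out$expected), 0)
  out <- out[order(out$promoter_bin, out$enhancer_bin),
             c("promoter_bin", "enhancer_bin", "distance", "observed",
               "expected", "intensity", "q")]
  rownames(out) <- NULL
  attr(out, "n_tests") <- n_tests
  out
}

#' Regulatory potential score per gene
#'
#' The RPS of a gene is the sum of interaction intensities
#' `log10(observed - expected)` over its significant promoter-enhancer
#' interactions; genes with no PEI score 0.
#'
#' @param peis a PEI data.frame from [call_peis()].
#' @param gene_map data.frame with columns `gene` and `promoter_bin`.
#' @param stage optional stage identifier.
#' @return data.frame: `gene`, `stage`, `rps`, `n_peis`.
#' @export
compute_rps <- function(peis, gene_map, stage = NA) {
  if (nrow(peis) && any(peis$observed - peis$expected <= 1))
    warning("PEI(s) with observed - expected <= 1: intensity floored at 0")
  rows <- lapply(unique(gene_map$gene), function(g) {
    pb <- gene_map$promoter_bin[gene_map$gene == g]
    sel <- peis$promoter_bin %in% pb
    data.frame(gene = g, stage = stage,
               rps = sum(peis$intensity[sel]), n_peis = sum(sel))
  })
  do.call(rbind, rows)
}

#' Differential regulatory potential between two stages
#'
#' A gene is flagged when both `|log2((rps_b + eps) / (rps_a + eps))| >
#' fc_cut` and `|rps_b - rps_a| > delta_cut` hold; the pseudocount `eps`
#' guards zero scores.
#'
#' @param rps_a,rps_b RPS tables ([compute_rps()]) of the two stages.
#' @param fc_cut log2 fold-change cutoff (default 1.5).
#' @param delta_cut absolute-difference cutoff (default 3).
#' @param eps pseudocount (default 0.1).
#' @return data.frame: `gene`, `rps_a`, `rps_b`, `log2fc`, `delta`,
#'   `flagged`, `direction`.
#' @export
differential_rps <- function(rps_a, rps_b, fc_cut = 1.5, delta_cut = 3,
                             eps = 0.1) {
  m <- merge(rps_a[, c("gene", "rps")], rps_b[, c("gene", "rps")],
             by = "gene", suffixes = c("_a", "_b"))
  m$log2fc <- log2((m$rps_b + eps) / (m$rps_a + eps))
  m$delta <- m$rps_b - m$rps_a
  m$flagged <- abs(m$log2fc) > fc_cut & abs(m$delta) > delta_cut
  m$direction <- ifelse(!m$flagged, "stable",
                        ifelse(m$delta > 0, "increased", "decreased"))
  m
}

#' K-means clustering of per-gene stage profiles
#'
#' Rows are z-scored across stages (constant rows map to zero) and
#' clustered by k-means with a fixed seed and multiple restarts; used for
#' both regulatory-potential (k = 6) and temporal-expression (k = 4)
#' profiles.
#'
#' @param mat numeric matrix, genes x stages.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param nstart k-means restarts (default 25).
#' @return list with `labels` (named by rownames) and `centers`.
#' @export
cluster_profiles <- function(mat, k, seed = 1L, nstart = 25) {
  if (nrow(mat) < k) stop("k exceeds the number of rows")
  z <- t(apply(mat, 1, function(r) {
    s <- stats::sd(r)
    if (is.na(s) || s == 0) r * 0 else (r - mean(r)) / s
  }))
  km <- with_seed(seed, stats::kmeans(z, centers = k, nstart = nstart,
                                      iter.max = 100))
  list(labels = stats::setNames(km$cluster, rownames(mat)),
       centers = km$centers)
}

#' Super-/regular-/poised-enhancer classification
#'
#' H3K27ac peaks within `stitch` bp of each other are merged; stitched
#' regions are ranked by total signal and, after scaling ranks and signals
#' to the unit square, the inflection point is the rank where a slope-1
#' tangent touches the curve (the point furthest below the diagonal).
#' Regions above the inflection point are super-enhancers (SE), the rest
#' regular enhancers (RE).  Regions contacting distal promoters
#' (`pei_regions`) that overlap no H3K27ac peak are poised enhancers (PE).
#'
#' @param peaks data.frame of peaks: `chrom`, `start`, `end`, `signal`.
#' @param stitch merge distance in bp (default 12500).
#' @param pei_regions optional data.frame of PEI-contacted regions
#'   (`chrom`, `start`, `end`) to derive PE annotations.
#' @return data.frame: `chrom`, `start`, `end`, `class`, `stitched_signal`,
#'   `n_peaks`.
#' @export
classify_enhancers <- function(peaks, stitch = 12500, pei_regions = NULL) {
  regions <- NULL
  if (nrow(peaks)) {
    pk <- peaks[order(peaks$start), ]
    cur <- pk[1, c("chrom", "start", "end", "signal")]
    cur$n_peaks <- 1L
    regions <- list()
    if (nrow(pk) > 1) for (k in 2:nrow(pk)) {
      if (pk$start[k] - cur$end <= stitch) {
        cur$end <- max(cur$end, pk$end[k])
        cur$signal <- cur$signal + pk$signal[k]
        cur$n_peaks <- cur$n_peaks + 1L
      } else {
        regions[[length(regions) + 1]] <- cur
        cur <- pk[k, c("chrom", "start", "end", "signal")]
        cur$n_peaks <- 1L
      }
    }
    regions[[length(regions) + 1]] <- cur
    regions <- do.call(rbind, regions)
    names(regions)[names(regions) == "signal"] <- "stitched_signal"
    if (nrow(regions) < 3) {
      warning("fewer than 3 stitched regions: inflection undefined, all RE")
      regions$class <- "RE"
    } else {
      o <- order(regions$stitched_signal)
      y <- regions$stitched_signal[o] / max(regions$stitched_signal)
      x <- seq_along(o) / length(o)
      cut_idx <- which.max(x - y)
      thr <- regions$stitched_signal[o][cut_idx]
      regions$class <- ifelse(regions$stitched_signal > thr, "SE", "RE")
    }
  }
  pe <- NULL
  if (!is.null(pei_regions) && nrow(pei_regions)) {
    overlaps_peak <- function(s, e) {
      nrow(peaks) > 0 && any(peaks$start < e & peaks$end > s)
    }
    hit <- mapply(overlaps_peak, pei_regions$start, pei_regions$end)
    if (any(!hit))
      pe <- data.frame(chrom = pei_regions$chrom[!hit],
                       start = pei_regions$start[!hit],
                       end = pei_regions$end[!hit],
                       class = "PE", stitched_signal = 0, n_peaks = 0L)
  }
  out <- rbind(if (!is.null(regions))
                 regions[, c("chrom", "start", "end", "class",
                             "stitched_signal", "n_peaks")], pe)
  if (is.null(out))
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), class = character(),
                      stitched_signal = numeric(), n_peaks = integer())
  rownames(out) <- NULL
  out
}

#' Chromatin loop calling
#'
#' Tests every unmasked cell in the 20 kb - 2 Mb separation range against
#' the map's spline-smoothed distance decay with a Poisson upper-tail test,
#' applies Benjamini-Hochberg correction, keeps `q < q_cut`, scores
#' strength as observed/expected and retains the `top_k` strongest calls.
#'
#' @param map a balanced [contact_map] (5 kb in the standard workflow).
#' @param min_d,max_d separation range in bp (defaults 20 kb and 2 Mb).
#' @param q_cut q-value cutoff (default 0.05).
#' @param top_k hard cap on reported loops, ranked by strength (default
#'   15000).
#' @return data.frame of loops: `anchor_i`, `anchor_j`, `distance`,
#'   `observed`, `expected`, `strength`, `q`; attribute `"n_tests"`.
#' @export
call_loops <- function(map, min_d = 20000, max_d = 2e6, q_cut = 0.05,
                       top_k = 15000) {
  if (!map$balanced) stop("map must be balanced")
  M <- map$mat
  n <- nrow(M)
  res <- map$resolution
  dmin <- max(1L, ceiling(min_d / res))
  dmax <- min(n - 1L, floor(max_d / res))
  keep <- !map$mask
  dec <- smooth_decay(diag_means(M, which(keep)))
  cells <- list()
  for (d in dmin:dmax) {
    i <- seq_len(n - d); j <- i + d
    ok <- keep[i] & keep[j]
    if (!any(ok)) next
    cells[[length(cells) + 1]] <- data.frame(
      anchor_i = i[ok], anchor_j = j[ok],
      observed = M[cbind(i[ok], j[ok])], expected = dec(d))
  }
  cc <- do.call(rbind, cells)
  cc$pval <- pois_upper_tail(cc$observed, cc$expected)
  cc$q <- stats::p.adjust(cc$pval, method = "BH")
  hits <- cc[cc$q < q_cut & cc$observed > cc$expected, ]
  hits$strength <- hits$observed / hits$expected
  hits <- hits[order(-hits$strength), ]
  if (nrow(hits) > top_k) hits <- hits[seq_len(top_k), ]
  hits$distance <- (hits$anchor_j - hits$anchor_i) * res
  out <- hits[, c("anchor_i", "anchor_j", "distance", "observed",
                  "expected", "strength", "q")]
  rownames(out) <- NULL
  attr(out, "n_tests") <- nrow(cc)
  out
}

#' CTCF orientation annotation of loops
#'
#' A loop is convergent when a forward (+) motif lies within `anchor_slop`
#' bins of its left anchor and a reverse (-) motif within `anchor_slop` of
#' its right anchor; otherwise divergent (- then +), tandem (same
#' orientation on both anchors) or absent (an anchor without any motif).
#'
#' @param loops loop data.frame from [call_loops()] (or any frame with
#'   `anchor_i`, `anchor_j` bins).
#' @param ctcf data.frame of CTCF motifs with columns `bin` (1-based) and
#'   `strand` in {"+", "-"}; alternatively BED-style `start` plus
#'   `resolution` to derive bins.
#' @param anchor_slop match tolerance in bins (default 1).
#' @param resolution bin width, required when `ctcf` has no `bin` column.
#' @return `loops` with an added `ctcf_orientation` column.
#' @export
convergent_filter <- function(loops, ctcf, anchor_slop = 1,
                              resolution = NULL) {
  if (!"strand" %in% names(ctcf) || any(!ctcf$strand %in% c("+", "-")))
    stop("CTCF motifs must carry a strand of '+' or '-'")
  if (!"bin" %in% names(ctcf)) {
    if (is.null(resolution)) stop("resolution required to bin CTCF positions")
    ctcf$bin <- floor(ctcf$start / resolution) + 1L
  }
  plus <- ctcf$bin[ctcf$strand == "+"]
  minus <- ctcf$bin[ctcf$strand == "-"]
  near <- function(bins, x) length(bins) > 0 && any(abs(bins - x) <= anchor_slop)
  loops$ctcf_orientation <- vapply(seq_len(nrow(loops)), function(k) {
    i <- loops$anchor_i[k]; j <- loops$anchor_j[k]
    lp <- near(plus, i); lm <- near(minus, i)
    rp <- near(plus, j); rm <- near(minus, j)
    if (!(lp || lm) || !(rp || rm)) "absent"
    else if (lp && rm) "convergent"
    else if (lm && rp) "divergent"
    else "tandem"
  }, character(1))
  loops
}

#' Fraction of enhancers skipping their nearest promoter
#'
#' For each enhancer bin engaged in a PEI, finds its nearest promoter by
#' linear distance; the enhancer is "skipping" when none of its interacting
#' promoters is at that minimal distance (ties count as nearest).
#'
#' @param peis PEI data.frame from [call_peis()].
#' @param promoters integer vector of all promoter bins.
#' @return the skipping fraction (NA when there are no PEIs).
#' @export
promoter_skip_fraction <- function(peis, promoters) {
  if (nrow(peis) == 0) return(NA_real_)
  ubins <- unique(peis$enhancer_bin)
  skip <- vapply(ubins, function(e) {
    dmin <- min(abs(promoters - e))
    partners <- peis$promoter_bin[peis$enhancer_bin == e]
    !any(abs(partners - e) == dmin)
  }, logical(1))
  mean(skip)
}
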