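#' Directionality index track
#'
#' For each bin with a full window on both sides, let `A` be the summed
#' balanced contacts to the `window` upstream bins and `B` to the `window`
#' downstream bins, `E = (A + B) / 2`; then
#' `DI = sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)`, and 0 when
#' `A = B = 0`.  Positive DI marks downstream bias (domain starts),
#' negative upstream bias (domain ends).
#'
#' @param map a balanced [contact_map].
#' @param window one-sided window in bins (default 10, i.e. +/-200 kb at
#'   20 kb resolution).
#' @return a `di_track` data.frame: `bin`, `di` (NA where the window does
#'   not fit or a masked bin is involved), attribute `window`.
#' @export
directionality_index <- function(map, window = 10) {
  M <- map$mat
  n <- nrow(M)
  di <- rep(NA_real_, n)
  for (b in (window + 1):(n - window)) {
    A <- sum(M[b, (b - window):(b - 1)])
    B <- sum(M[b, (b + 1):(b + window)])
    if (A == 0 && B == 0) { di[b] <- 0; next }
    E <- (A + B) / 2
    di[b] <- sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
  }
  di[map$mask] <- NA
  out <- data.frame(bin = seq_len(n), di = di)
  attr(out, "window") <- window
  class(out) <- c("di_track", "data.frame")
  out
}

#' Insulation score track
#'
#' `is_raw(b)` is the mean balanced contact in the `window x window` square
#' spanning the `window` bins upstream by the `window` bins downstream of
#' bin `b`; `is_norm = log2(is_raw / mean(is_raw))` over the chromosome.
#' Local minima of `is_norm` mark insulating boundaries.
#'
#' @param map a balanced [contact_map].
#' @param window one-sided window in bins (default 10).
#' @return an `is_track` data.frame: `bin`, `is_raw`, `is_norm`.
#' @export
insulation_score <- function(map, window = 10) {
  M <- map$mat
  n <- nrow(M)
  is_raw <- rep(NA_real_, n)
  for (b in (window + 1):(n - window)) {
    is_raw[b] <- mean(M[(b - window):(b - 1), (b + 1):(b + window)])
  }
  is_raw[map$mask] <- NA
  mu <- mean(is_raw[is_raw > 0], na.rm = TRUE)
  is_norm <- log2(is_raw / mu)
  is_norm[!is.na(is_raw) & is_raw == 0] <- NA
  out <- data.frame(bin = seq_len(n), is_raw = is_raw, is_norm = is_norm)
  attr(out, "window") <- window
  class(out) <- c("is_track", "data.frame")
  out
}

## ---- 3-state Gaussian hidden Markov model (EM + Viterbi) ----------------

fit_gaussian_hmm <- function(x, n_states = 3, max_iter = 200, tol = 1e-6) {
  n <- length(x)
  # tercile initialization: deterministic, orders states by emission mean
  qs <- stats::quantile(x, seq_len(n_states - 1) / n_states)
  grp <- findInterval(x, qs) + 1L
  mu <- tapply(x, grp, mean)
  sd0 <- pmax(tapply(x, grp, stats::sd), stats::sd(x) / 20, 1e-8)
  mu <- as.numeric(mu); sd0 <- as.numeric(sd0)
  if (length(mu) < n_states) stop("degenerate initialization: too few distinct values")
  trans <- matrix(0.05 / (n_states - 1), n_states, n_states)
  diag(trans) <- 0.95
  init <- rep(1 / n_states, n_states)
  loglik_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- sapply(seq_len(n_states), function(s)
      stats::dnorm(x, mu[s], sd0[s]))
    dens <- pmax(dens, 1e-300)
    # scaled forward-backward
    alpha <- matrix(0, n, n_states); scale <- numeric(n)
    a <- init * dens[1, ]; scale[1] <- sum(a); alpha[1, ] <- a / scale[1]
    for (t in 2:n) {
      a <- (alpha[t - 1, ] %*% trans) * dens[t, ]
      scale[t] <- sum(a); alpha[t, ] <- a / scale[t]
    }
    beta <- matrix(0, n, n_states); beta[n, ] <- 1
    for (t in (n - 1):1)
      beta[t, ] <- (trans %*% (dens[t + 1, ] * beta[t + 1, ])) / scale[t + 1]
    gamma <- alpha * beta
    gamma <- gamma / rowSums(gamma)
    xi_num <- matrix(0, n_states, n_states)
    for (t in 1:(n - 1)) {
      xi <- (alpha[t, ] %o% (dens[t + 1, ] * beta[t + 1, ])) * trans
      xi_num <- xi_num + xi / sum(xi)
    }
    loglik <- sum(log(scale))
    init <- gamma[1, ]
    trans <- xi_num / rowSums(xi_num)
    mu <- colSums(gamma * x) / colSums(gamma)
    sd0 <- sqrt(colSums(gamma * (outer(x, mu, "-"))^2) / colSums(gamma))
    sd0 <- pmax(sd0, stats::sd(x) / 100, 1e-8)
    if (abs(loglik - loglik_old) < tol * (1 + abs(loglik_old))) {
      loglik_old <- loglik
      break
    }
    loglik_old <- loglik
    if (iter == max_iter)
      stop("HMM EM did not converge in ", max_iter, " iterations")
  }
  # Viterbi
  dens <- pmax(sapply(seq_len(n_states), function(s)
    stats::dnorm(x, mu[s], sd0[s])), 1e-300)
  lv <- matrix(-Inf, n, n_states); ptr <- matrix(0L, n, n_states)
  lv[1, ] <- log(init) + log(dens[1, ])
  ltr <- log(trans)
  for (t in 2:n) {
    for (s in seq_len(n_states)) {
      v <- lv[t - 1, ] + ltr[, s]
      ptr[t, s] <- which.max(v)
      lv[t, s] <- max(v) + log(dens[t, s])
    }
  }
  path <- integer(n)
  path[n] <- which.max(lv[n, ])
  for (t in (n - 1):1) path[t] <- ptr[t + 1, path[t + 1]]
  # relabel so state 1 = most negative mean, 3 = most positive
  ord <- order(mu)
  relabel <- match(seq_len(n_states), ord)
  list(states = relabel[path], means = mu[ord], sds = sd0[ord],
       loglik = loglik_old, iterations = iter)
}

#' DI segmentation with a hidden Markov model
#'
#' Fits a 3-state Gaussian HMM (upstream-biased / unbiased /
#' downstream-biased, ordered by emission mean) to the defined stretch of
#' the DI track by EM with deterministic tercile initialization, decodes
#' the most probable state path, and assembles domains: a domain spans from
#' the first bin of a downstream-biased run to the last bin of the
#' subsequent upstream-biased run(s) before the next downstream run.
#'
#' @param di a `di_track` from [directionality_index()].
#' @param seed integer; kept for interface stability (the fit itself is
#'   deterministic).
#' @param min_domain minimum domain span in bins; domains narrower than
#'   this are merged into an adjacent domain, dropping the boundary with
#'   the weaker DI sign-jump.  Defaults to the DI window, the narrowest
#'   span the statistic can support.
#' @return a `tad_set`: list with `domains` (data.frame start_bin, end_bin,
#'   source = "DI"), `boundaries` (sorted interior boundary bins: domain
#'   starts and ends+1), `states` (full-length state vector, NA off-track).
#' @export
hmm_segment <- function(di, seed = 1L, min_domain = attr(di, "window")) {
  ok <- which(!is.na(di$di))
  if (length(ok) < 3 * attr(di, "window")) stop("DI track too short for segmentation")
  # variance-stabilize the heavy-tailed DI (monotone, sign-preserving) so
  # the Gaussian emissions are well behaved
  x <- sign(di$di[ok]) * log1p(abs(di$di[ok]))
  states_full <- rep(NA_integer_, nrow(di))
  if (stats::sd(x) == 0) {
    # flat track: everything in the unbiased state, no domains
    states_full[ok] <- 2L
    return(new_tad_set(data.frame(start_bin = integer(), end_bin = integer(),
                                  source = character()),
                       n = nrow(di), states = states_full))
  }
  fit <- fit_gaussian_hmm(x)
  states_full[ok] <- fit$states
  s <- fit$states
  # run-length view of the decoded path
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  domains <- list()
  cur_start <- NA_integer_; last_up_end <- NA_integer_
  for (k in seq_along(r$values)) {
    v <- r$values[k]
    if (v == 3L) {                       # downstream-biased: domain start
      if (!is.na(cur_start) && !is.na(last_up_end)) {
        domains[[length(domains) + 1]] <- c(cur_start, last_up_end)
        cur_start <- NA_integer_
      }
      if (is.na(cur_start)) { cur_start <- starts[k]; last_up_end <- NA_integer_ }
    } else if (v == 1L) {                # upstream-biased: extends the end
      if (!is.na(cur_start)) last_up_end <- ends[k]
    }
  }
  if (!is.na(cur_start) && !is.na(last_up_end))
    domains[[length(domains) + 1]] <- c(cur_start, last_up_end)
  dom <- if (length(domains)) {
    m <- do.call(rbind, domains)
    data.frame(start_bin = ok[m[, 1]], end_bin = ok[m[, 2]], source = "DI")
  } else data.frame(start_bin = integer(), end_bin = integer(),
                    source = character())
  dom <- merge_subwindow_domains(dom, di, min_domain)
  new_tad_set(dom, n = nrow(di), states = states_full, hmm = fit)
}

## A DI track with a +/-w window cannot support domains narrower than the
## window itself; merge such fragments into an adjacent domain, dropping
## whichever boundary shows the weaker DI sign-jump.
merge_subwindow_domains <- function(dom, di, min_domain) {
  if (nrow(dom) < 2 || min_domain <= 1) return(dom)
  jump <- function(b) {           # boundary strength: DI step across bin b
    x <- sign(di$di) * log1p(abs(di$di))
    if (b <= 1 || is.na(x[b]) || is.na(x[b - 1])) return(Inf)
    x[b] - x[b - 1]
  }
  repeat {
    len <- dom$end_bin - dom$start_bin + 1
    k <- which(len < min_domain)
    if (!length(k)) break
    k <- k[1]
    left_adj <- k > 1 && dom$end_bin[k - 1] + 1L == dom$start_bin[k]
    right_adj <- k < nrow(dom) && dom$end_bin[k] + 1L == dom$start_bin[k + 1]
    if (!left_adj && !right_adj) {
      dom <- dom[-k, , drop = FALSE]
    } else if (left_adj &&
               (!right_adj || jump(dom$start_bin[k]) <= jump(dom$start_bin[k + 1]))) {
      dom$end_bin[k - 1] <- dom$end_bin[k]      # own start was the weak edge
      dom <- dom[-k, , drop = FALSE]
    } else {
      dom$end_bin[k] <- dom$end_bin[k + 1]      # next start was the weak edge
      dom <- dom[-(k + 1), , drop = FALSE]
    }
    if (nrow(dom) < 2) break
  }
  rownames(dom) <- NULL
  dom
}

new_tad_set <- function(domains, n, states = NULL, hmm = NULL) {
  if (nrow(domains) > 1) {
    domains <- domains[order(domains$start_bin), ]
    if (any(domains$start_bin[-1] <= domains$end_bin[-nrow(domains)]))
      stop("TAD partition violated: overlapping domains")
  }
  b <- sort(unique(c(domains$start_bin, domains$end_bin + 1L)))
  b <- b[b > 1 & b <= n]
  structure(list(domains = domains, boundaries = b, n_bins = n,
                 states = states, hmm = hmm), class = "tad_set")
}

#' @export
print.tad_set <- function(x, ...) {
  cat(sprintf("tad_set: %d domains, %d boundaries over %d bins\n",
              nrow(x$domains), length(x$boundaries), x$n_bins))
  invisible(x)
}

# interior local minima of v within [from, to] with two-sided prominence
local_minima <- function(v, from, to, prominence) {
  idx <- integer(0)
  for (b in (from + 1):(to - 1)) {
    if (is.na(v[b])) next
    l <- v[(from):(b - 1)]; r <- v[(b + 1):to]
    if (all(is.na(l)) || all(is.na(r))) next
    if (v[b] <= min(l, na.rm = TRUE) && v[b] <= min(r, na.rm = TRUE)) {
      prom <- min(max(l, na.rm = TRUE), max(r, na.rm = TRUE)) - v[b]
      if (prom >= prominence) idx <- c(idx, b)
    }
  }
  idx
}

#' Hybrid TAD calling: DI-HMM domains refined by insulation minima
#'
#' Calls domains by DI-HMM segmentation, then subdivides any domain larger
#' than `max_di_tad_size` at interior local minima of the normalized
#' insulation score whose prominence exceeds `is_prominence` (log2 units).
#'
#' @param map a balanced 20 kb [contact_map].
#' @param di_window,is_window one-sided windows in bins.
#' @param max_di_tad_size domains larger than this (bp) are candidates for
#'   subdivision (default 1 Mb).
#' @param is_prominence minimum prominence of an insulation minimum
#'   (default 0.1).
#' @param seed passed to [hmm_segment()].
#' @return a `tad_set`; subdivided domains carry source `"IS"`.
#' @export
call_tads <- function(map, di_window = 10, is_window = 10,
                      max_di_tad_size = 1e6, is_prominence = 0.1, seed = 1L) {
  di <- directionality_index(map, di_window)
  base <- hmm_segment(di, seed)
  ist <- insulation_score(map, is_window)
  max_bins <- max_di_tad_size / map$resolution
  out <- list()
  for (k in seq_len(nrow(base$domains))) {
    d <- base$domains[k, ]
    len <- d$end_bin - d$start_bin + 1
    if (len <= max_bins || len < 7) { out[[length(out) + 1]] <- d; next }
    splits <- local_minima(ist$is_norm, d$start_bin + 2L, d$end_bin - 2L,
                           is_prominence)
    if (length(splits) == 0) { out[[length(out) + 1]] <- d; next }
    cuts <- c(d$start_bin, splits, d$end_bin + 1L)
    for (m in seq_len(length(cuts) - 1)) {
      out[[length(out) + 1]] <- data.frame(
        start_bin = cuts[m], end_bin = cuts[m + 1] - 1L,
        source = if (length(splits)) "IS" else "DI")
    }
  }
  dom <- if (length(out)) do.call(rbind, out) else base$domains
  new_tad_set(dom, n = nrow(map$mat), states = base$states, hmm = base$hmm)
}

#' Boundary overlap between two TAD sets
#'
#' A boundary of `a` is shared if any boundary of `b` lies within
#' `tol_bins`, and vice versa.
#'
#' @param a,b `tad_set`s or integer boundary vectors on the same bin table.
#' @param tol_bins match tolerance in bins (default 1).
#' @return list with shared/specific counts, fractions, and the specific
#'   boundary bins of each set.
#' @export
boundary_overlap <- function(a, b, tol_bins = 1) {
  ba <- if (inherits(a, "tad_set")) a$boundaries else sort(unique(as.integer(a)))
  bb <- if (inherits(b, "tad_set")) b$boundaries else sort(unique(as.integer(b)))
  ma <- vapply(ba, function(x) any(abs(bb - x) <= tol_bins), logical(1))
  mb <- vapply(bb, function(x) any(abs(ba - x) <= tol_bins), logical(1))
  list(n_a = length(ba), n_b = length(bb),
       n_shared_a = sum(ma), n_shared_b = sum(mb),
       shared_fraction_a = if (length(ba)) mean(ma) else NA,
       shared_fraction_b = if (length(bb)) mean(mb) else NA,
       specific_a = ba[!ma], specific_b = bb[!mb])
}

#' Permutation test for stage-specific boundaries
#'
#' For each candidate boundary (typically one called in exactly one of two
#' stages), the observed statistic is the Spearman correlation of the two
#' stages' DI profiles over the 21 bins centered on the boundary
#' (+/- `window`).  The null distribution is built from `n_perm` Spearman
#' correlations of the two DI tracks over 20 bins selected at random
#' (scattered, without replacement).  A boundary is flagged specific when
#' its observed correlation does not exceed the null's 95th percentile,
#' i.e. its cross-stage DI concordance is indistinguishable from chance.
#'
#' @param di_a,di_b `di_track`s of the two stages on the same bin table.
#' @param candidates integer bin positions of candidate boundaries.
#' @param window one-sided profile window in bins (default 10).
#' @param n_perm number of random selections (default 1000).
#' @param n_random_bins bins per random selection (default 20).
#' @param seed integer seed; the null is deterministic given it.
#' @return data.frame: `boundary`, `r_obs`, `p_emp` (fraction of null >=
#'   observed), `specific`; candidates too close to the track edge are
#'   dropped with a warning.  The null 95th percentile is attached as
#'   attribute `"null_q95"`.
#' @export
specific_boundary_test <- function(di_a, di_b, candidates, window = 10,
                                   n_perm = 1000, n_random_bins = 20,
                                   seed = 1L) {
  ok <- which(!is.na(di_a$di) & !is.na(di_b$di))
  null_r <- with_seed(seed, vapply(seq_len(n_perm), function(k) {
    sel <- sample(ok, n_random_bins)
    suppressWarnings(stats::cor(di_a$di[sel], di_b$di[sel], method = "spearman"))
  }, numeric(1)))
  null_r[is.na(null_r)] <- 0
  q95 <- stats::quantile(null_r, 0.95, names = FALSE)
  lo <- min(ok); hi <- max(ok)
  usable <- candidates >= lo + window & candidates <= hi - window
  if (any(!usable))
    warning(sum(!usable), " candidate boundary(ies) within ", window,
            " bins of the track edge excluded")
  res <- lapply(candidates[usable], function(b) {
    w <- (b - window):(b + window)
    r <- suppressWarnings(stats::cor(di_a$di[w], di_b$di[w], method = "spearman"))
    if (is.na(r)) r <- 0
    data.frame(boundary = b, r_obs = r,
               p_emp = mean(null_r >= r),
               specific = r <= q95)
  })
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(boundary = integer(), r_obs = numeric(),
               p_emp = numeric(), specific = logical())
  attr(out, "null_q95") <- q95
  out
}

#' Consensus TADs across stages and replicates
#'
#' Retains boundaries present (within `tol_bins`) in at least
#' `min_fraction` of all samples, merges retained positions closer than
#' `tol_bins` (median position), and forms consensus domains as the
#' intervals between successive retained boundaries (chromosome ends
#' included as implicit boundaries).
#'
#' @param all_sets non-empty list of `tad_set`s (or boundary vectors) on a
#'   common bin table.
#' @param min_fraction minimum support fraction (default 0.5).
#' @param tol_bins match tolerance in bins (default 1).
#' @param n_bins chromosome length in bins (required when passing raw
#'   vectors).
#' @return a `tad_set` of consensus domains (source `"consensus"`).
#' @export
consensus_tads <- function(all_sets, min_fraction = 0.5, tol_bins = 1,
                           n_bins = NULL) {
  if (length(all_sets) == 0) stop("empty input: no TAD sets")
  blists <- lapply(all_sets, function(s)
    if (inherits(s, "tad_set")) s$boundaries else sort(unique(as.integer(s))))
  if (is.null(n_bins))
    n_bins <- max(vapply(all_sets, function(s)
      if (inherits(s, "tad_set")) s$n_bins else max(s, 0L), numeric(1)))
  cand <- sort(unique(unlist(blists)))
  support <- vapply(cand, function(x)
    mean(vapply(blists, function(b) any(abs(b - x) <= tol_bins), logical(1))),
    numeric(1))
  kept <- cand[support >= min_fraction]
  # merge retained candidates closer than tol into one position
  merged <- integer(0)
  while (length(kept)) {
    grp <- kept[kept - kept[1] <= tol_bins]
    merged <- c(merged, as.integer(round(stats::median(grp))))
    kept <- kept[!(kept %in% grp)]
  }
  edges <- unique(c(1L, merged, n_bins + 1L))
  dom <- data.frame(start_bin = edges[-length(edges)],
                    end_bin = edges[-1] - 1L,
                    source = "consensus")
  dom$ctad_id <- sprintf("cTAD%03d", seq_len(nrow(dom)))
  new_tad_set(dom, n = n_bins)
}

#' A/B classification of a TAD
#'
#' A domain is an A-TAD when more than `frac` (default 70%) of its
#' analyzable bins lie in compartment A, otherwise a B-TAD.  In strict mode
#' the B call additionally requires more than `frac` B bins, with "mixed"
#' for the remainder.
#'
#' @param tad vector or one-row data.frame with `start_bin`, `end_bin`.
#' @param profile a `compartment_profile`.
#' @param frac membership threshold (default 0.7).
#' @param strict logical; see above.
#' @return one of "A-TAD", "B-TAD", "mixed".
#' @export
classify_tad_compartment <- function(tad, profile, frac = 0.7, strict = FALSE) {
  s <- if (is.data.frame(tad)) tad$start_bin else tad[1]
  e <- if (is.data.frame(tad)) tad$end_bin else tad[2]
  lab <- profile$label[s:e]
  lab <- lab[lab != "masked"]
  if (length(lab) == 0) return("mixed")
  fa <- mean(lab == "A")
  if (fa > frac) return("A-TAD")
  if (!strict) return("B-TAD")
  if (mean(lab == "B") > frac) "B-TAD" else "mixed"
}

#' Domain scores of consensus TADs
#'
#' The D-score of a domain is the fraction of all intrachromosomal contacts
#' (upper triangle including the diagonal) with both ends inside the
#' domain.  Disjoint domains therefore have D-scores summing to at most 1.
#'
#' @param map a balanced [contact_map].
#' @param ctads a `tad_set` of consensus domains.
#' @param stage,replicate identifiers copied to the rows.
#' @return data.frame: `ctad_id`, `stage`, `replicate`, `d_score`.
#' @export
domain_score <- function(map, ctads, stage = NA, replicate = NA) {
  M <- map$mat
  ut <- upper.tri(M, diag = TRUE)
  total <- sum(M[ut])
  rows <- lapply(seq_len(nrow(ctads$domains)), function(k) {
    d <- ctads$domains[k, ]
    idx <- d$start_bin:d$end_bin
    if (length(idx) == 0 || total == 0) {
      warning("empty TAD or empty map: d_score = 0")
      ds <- 0
    } else {
      sub <- M[idx, idx, drop = FALSE]
      ds <- sum(sub[upper.tri(sub, diag = TRUE)]) / total
    }
    data.frame(ctad_id = if (!is.null(d$ctad_id)) d$ctad_id else
                 sprintf("cTAD%03d", k),
               stage = stage, replicate = replicate, d_score = ds)
  })
  do.call(rbind, rows)
}

#' Differential domain-score test between two stages
#'
#' Per consensus domain, compares replicate D-scores between the two stages
#' with a two-sample t test (Welch by default) and flags domains with
#' `p < alpha` as increased or decreased by the sign of the mean
#' difference.  Degenerate cases: identical constant values give p = 1;
#' unequal constants are flagged with a degenerate-variance warning.
#'
#' @param table data.frame from [domain_score()] rows across stages and
#'   replicates.
#' @param stage_pair length-2 character vector (reference, comparison).
#' @param alpha significance cutoff (default 0.05).
#' @param var_equal use the pooled-variance t test instead of Welch.
#' @return data.frame: `ctad_id`, `mean_a`, `mean_b`, `t`, `p`,
#'   `direction`, `flagged`.
#' @export
differential_dscore <- function(table, stage_pair, alpha = 0.05,
                                var_equal = FALSE) {
  ids <- unique(table$ctad_id)
  rows <- lapply(ids, function(id) {
    x <- table$d_score[table$ctad_id == id & table$stage == stage_pair[1]]
    y <- table$d_score[table$ctad_id == id & table$stage == stage_pair[2]]
    if (length(x) < 2 || length(y) < 2)
      stop("need >= 2 replicates per stage for the differential test")
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        tt <- list(statistic = 0, p.value = 1)
      } else {
        warning("degenerate variance with unequal means for ", id)
        tt <- list(statistic = sign(mean(y) - mean(x)) * Inf, p.value = 0)
      }
    } else {
      ht <- stats::t.test(y, x, var.equal = var_equal)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    data.frame(ctad_id = id, mean_a = mean(x), mean_b = mean(y),
               t = tt$statistic, p = tt$p.value,
               direction = if (mean(y) > mean(x)) "increased" else
                 if (mean(y) < mean(x)) "decreased" else "none",
               flagged = tt$p.value < alpha)
  })
  do.call(rbind, rows)
}
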