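#' Pearson correlation matrix of an O/E map
#'
#' Correlates bin profiles of the observed/expected matrix over unmasked
#' bins.  Missing O/E cells (zero expectation) are treated as no signal
#' (replaced by the neutral value 1 before correlating); constant columns
#' are masked out.
#'
#' @param map a balanced [contact_map] (the O/E transform is applied
#'   internally unless the map already carries the `"oe"` attribute).
#' @return list with `cor` (correlation matrix over kept bins) and `keep`
#'   (indices of kept bins).
#' @keywords internal
oe_correlation <- function(map) {
  oe <- if (isTRUE(attr(map, "oe"))) map else observed_over_expected(map)
  keep <- which(!map$mask)
  X <- oe$mat[keep, keep, drop = FALSE]
  X[is.na(X)] <- 1
  v <- apply(X, 2, stats::var)
  nz <- v > 0
  keep <- keep[nz]
  if (length(keep) < 3) stop("correlation undefined: fewer than 3 variable bins")
  C <- stats::cor(X[nz, nz, drop = FALSE])
  list(cor = C, keep = keep)
}

#' Von Neumann entropy of a correlation spectrum
#'
#' Entropy of the trace-normalized eigenvalue spectrum of a positive
#' semidefinite matrix, normalized by `log(n)` so that independent bins
#' (identity correlation) give 1 and a rank-one correlation gives 0.
#'
#' @param C symmetric positive semidefinite matrix (e.g. a correlation
#'   matrix).
#' @return normalized entropy in \[0, 1\].
#' @export
vne_from_correlation <- function(C) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  if (sum(ev) <= 0) stop("degenerate spectrum")
  p <- ev / sum(ev)
  p <- p[p > 0]
  -sum(p * log(p)) / log(nrow(C))
}

#' Von Neumann entropy of a contact map
#'
#' Builds the Pearson correlation matrix of the observed/expected map and
#' returns the normalized entropy of its eigenvalue spectrum.  Higher values
#' mean a more disordered (less structured) architecture; an identity-like
#' correlation gives 1 and a perfectly coherent (rank-one) one gives 0.
#'
#' @param map a balanced [contact_map] with at least 3 unmasked bins.
#' @param stage,replicate optional identifiers copied to the result.
#' @return data.frame with columns `stage`, `replicate`, `vne`.
#' @export
von_neumann_entropy <- function(map, stage = NA, replicate = NA) {
  oc <- oe_correlation(map)
  data.frame(stage = stage, replicate = replicate,
             vne = vne_from_correlation(oc$cor))
}

#' A/B compartment calling from the leading eigenvector
#'
#' Computes the first principal component of the Pearson correlation matrix
#' of the O/E map, orients its sign so that its Spearman correlation with an
#' orientation track (gene density, or GC content) is positive, and labels
#' bins A where PC1 > 0 and B otherwise.
#'
#' @param map a balanced 20 kb [contact_map].
#' @param orientation_track per-bin numeric track (same length as the map)
#'   whose high values mark active chromatin (gene density or GC content).
#' @param stage optional stage identifier.
#' @param min_bins minimum unmasked bins required (default 20).
#' @return a `compartment_profile` data.frame: `bin` (1-based), `pc1`,
#'   `label` in {A, B, masked}, plus attribute `stage`.
#' @export
compute_pc1 <- function(map, orientation_track, stage = NA, min_bins = 20) {
  n <- nrow(map$mat)
  stopifnot(length(orientation_track) == n)
  oc <- oe_correlation(map)
  if (length(oc$keep) < min_bins)
    stop("chromosome skipped: fewer than ", min_bins, " unmasked bins")
  v <- eigen(oc$cor, symmetric = TRUE)$vectors[, 1]
  rho <- stats::cor(v, orientation_track[oc$keep], method = "spearman")
  if (!is.na(rho) && rho < 0) v <- -v
  pc1 <- rep(NA_real_, n)
  pc1[oc$keep] <- v
  label <- ifelse(is.na(pc1), "masked", ifelse(pc1 > 0, "A", "B"))
  out <- data.frame(bin = seq_len(n), pc1 = pc1, label = label)
  attr(out, "stage") <- stage
  class(out) <- c("compartment_profile", "data.frame")
  out
}

#' Cross-stage compartment switch classification
#'
#' Assigns each bin analyzable in all three stages a three-letter A/B
#' pattern (stage order as given), merges runs of identical pattern into
#' segments, and summarizes genome span per pattern.  AAB/ABB/BAA/BBA are
#' unidirectional switches, ABA/BAB transient, AAA/BBB stable.
#'
#' @param profiles list of exactly three `compartment_profile`s in stage
#'   order.
#' @param bins bin table of the underlying map (for bp lengths).
#' @return list with `segments` (data.frame: start_bin, end_bin, start_bp,
#'   end_bp, pattern, class, length_bp) and `summary` (per-pattern Mb and
#'   fraction of analyzable genome).
#' @export
classify_switches <- function(profiles, bins) {
  stopifnot(length(profiles) == 3)
  labs <- sapply(profiles, function(p) p$label)
  ok <- apply(labs != "masked", 1, all)
  n <- nrow(labs)
  pattern <- rep(NA_character_, n)
  pattern[ok] <- apply(labs[ok, , drop = FALSE], 1, paste, collapse = "")
  cls <- function(p) {
    if (p %in% c("AAA", "BBB")) "stable"
    else if (p %in% c("AAB", "ABB", "BAA", "BBA")) "unidirectional"
    else "transient"
  }
  segs <- list()
  i <- 1
  while (i <= n) {
    if (is.na(pattern[i])) { i <- i + 1; next }
    j <- i
    while (j < n && !is.na(pattern[j + 1]) && pattern[j + 1] == pattern[i]) j <- j + 1
    segs[[length(segs) + 1]] <- data.frame(
      start_bin = i, end_bin = j,
      start_bp = bins$start[i], end_bp = bins$end[j],
      pattern = pattern[i], class = cls(pattern[i]),
      length_bp = bins$end[j] - bins$start[i])
    i <- j + 1
  }
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(start_bin = integer(), end_bin = integer(),
               start_bp = numeric(), end_bp = numeric(),
               pattern = character(), class = character(),
               length_bp = numeric())
  tot <- sum(segments$length_bp)
  summary <- stats::aggregate(length_bp ~ pattern + class, segments, sum)
  summary$mb <- summary$length_bp / 1e6
  summary$fraction <- if (tot > 0) summary$length_bp / tot else NA
  list(segments = segments, summary = summary,
       analyzable_bp = tot,
       switched_fraction = if (tot > 0)
         sum(summary$fraction[summary$class != "stable"]) else NA)
}

#' Two-sided Wilcoxon rank-sum comparison of groups
#'
#' Thin wrapper over the Mann-Whitney U test used for all group-wise
#' expression comparisons (A vs B compartments, switch categories, domain
#' score tertiles, regulatory-potential tertiles).  Exact p for small
#' untied samples, normal approximation with tie correction otherwise.
#'
#' @param x,y numeric vectors (at least 2 observations each).
#' @return data.frame with `U` and two-sided `p`.
#' @export
compare_groups_expression <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 observations")
  wt <- stats::wilcox.test(x, y, alternative = "two.sided", exact = NULL)
  data.frame(U = unname(wt$statistic), p = wt$p.value)
}
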