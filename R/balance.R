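#' Knight-Ruiz-style matrix balancing
#'
#' Balances a symmetric contact matrix by a diagonal scaling
#' `D M D` so that every unmasked row sum equals a common target, here the
#' mean pre-balancing marginal (preserving the total count scale so balanced
#' entries remain interpretable as counts for Poisson-style tests).  Rows
#' with zero marginal are masked before balancing; optionally the sparsest
#' nonzero rows are masked too, since near-empty rows destabilize the
#' iteration.
#'
#' The scaling vector is found by the symmetric fixed-point iteration
#' `x <- x * sqrt(target / rowsum(DMD))`, the classical
#' Sinkhorn/Knight-Ruiz family for doubly-stochastic-like scaling of
#' symmetric non-negative matrices.
#'
#' @param map an unbalanced [contact_map].
#' @param tol convergence tolerance on the maximum relative row-sum
#'   deviation (default 1e-10).
#' @param max_iter maximum iterations (default 3000).
#' @param mask_quantile additionally mask unmasked rows whose nonzero
#'   marginal falls in this lower quantile (default 0 = none; e.g. 0.005).
#' @return a balanced [contact_map]; masked rows/columns are zeroed and
#'   recorded in `$mask`.  The scaling vector is attached as attribute
#'   `"scaling"`.
#' @export
kr_balance <- function(map, tol = 1e-10, max_iter = 3000, mask_quantile = 0) {
  # balancing an already balanced map is a (near) no-op by idempotence
  M <- map$mat
  n <- nrow(M)
  marg <- rowSums(M)
  mask <- map$mask | marg == 0
  if (mask_quantile > 0) {
    nz <- marg[!mask]
    cut <- stats::quantile(nz, mask_quantile)
    mask <- mask | (marg <= cut & !mask & marg <= cut)
  }
  keep <- which(!mask)
  if (length(keep) < 2) stop("fewer than 2 unmasked rows; cannot balance")
  A <- M[keep, keep, drop = FALSE]
  target <- mean(rowSums(A))
  x <- rep(1, length(keep))
  converged <- FALSE
  resid <- Inf
  for (iter in seq_len(max_iter)) {
    rs <- x * as.vector(A %*% x)
    if (any(rs == 0)) stop("zero row sum encountered during balancing")
    resid <- max(abs(rs - target)) / target
    if (resid < tol) { converged <- TRUE; break }
    x <- x * sqrt(target / rs)
  }
  if (!converged)
    stop(sprintf("KR balancing did not converge in %d iterations (relative residual %.3g)",
                 max_iter, resid))
  B <- matrix(0, n, n)
  B[keep, keep] <- A * outer(x, x)
  scaling <- rep(NA_real_, n)
  scaling[keep] <- x
  out <- contact_map(B, map$bins, map$resolution, map$chrom,
                     balanced = TRUE, mask = mask)
  attr(out, "scaling") <- scaling
  out
}

#' Distance-decay expectation of a balanced map
#'
#' For each bin separation `d = j - i` (0 .. n-1), the expected contact is
#' the mean balanced count over all unmasked pairs at that separation,
#' including zero cells.
#'
#' @param map a balanced [contact_map].
#' @return data.frame with columns `distance_bin` and `expected` (class
#'   `decay_profile`).
#' @export
expected_by_distance <- function(map) {
  if (!map$balanced) stop("map must be balanced")
  M <- map$mat
  keep <- which(!map$mask)
  n <- nrow(M)
  expected <- numeric(n)
  idx <- logical(n)
  idx[keep] <- TRUE
  for (d in 0:(n - 1)) {
    i <- seq_len(n - d)
    j <- i + d
    ok <- idx[i] & idx[j]
    expected[d + 1] <- if (any(ok)) mean(M[cbind(i[ok], j[ok])]) else 0
  }
  structure(data.frame(distance_bin = 0:(n - 1), expected = expected),
            class = c("decay_profile", "data.frame"))
}

#' Observed/expected transform
#'
#' Divides every cell by the distance-decay expectation at its separation.
#' Cells whose expectation is zero, or with a masked endpoint, are set to
#' `NA`.  By construction the mean of each diagonal stratum over non-missing
#' cells is 1 when `decay` comes from the same map.
#'
#' @param map a balanced [contact_map].
#' @param decay a decay profile from [expected_by_distance()]; defaults to
#'   the map's own.
#' @return a [contact_map] of O/E ratios (attribute `"oe"` set), `NA` where
#'   undefined.
#' @export
observed_over_expected <- function(map, decay = NULL) {
  if (!map$balanced) stop("map must be balanced")
  if (is.null(decay)) decay <- expected_by_distance(map)
  n <- nrow(map$mat)
  if (nrow(decay) != n) stop("decay profile length does not match map")
  dmat <- abs(outer(seq_len(n), seq_len(n), "-"))
  E <- matrix(decay$expected[dmat + 1], n, n)
  OE <- map$mat / E
  OE[E == 0] <- NA
  OE[map$mask, ] <- NA
  OE[, map$mask] <- NA
  out <- map
  out$mat <- OE
  attr(out, "oe") <- TRUE
  # skip symmetry/positivity validation: NA cells are legitimate here
  out
}
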