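#' Binned intrachromosomal contact map
#'
#' A `contact_map` holds a symmetric, binned Hi-C contact matrix for a single
#' chromosome together with its bin table.  Bins are fixed-width, 0-based,
#' half-open intervals (`bin_id = floor(start / resolution)`); the last bin of
#' a chromosome may be shorter and is flagged.  Internally the matrix is
#' stored dense (one chromosome at 20 kb or 5 kb rarely exceeds a few
#' thousand bins); entries are folded to the upper triangle on input and the
#' lower triangle is implied by symmetry.
#'
#' @param mat numeric symmetric matrix of non-negative counts.
#' @param bins data.frame with columns `chrom`, `start`, `end`, `bin_id`
#'   (dense 0..n-1).
#' @param resolution bin width in base pairs.
#' @param chrom chromosome identifier (one per map).
#' @param balanced logical; whether `mat` has been matrix-balanced.
#' @param mask logical vector of length n; `TRUE` marks bins excluded from
#'   analysis (e.g. zero-marginal rows).
#'
#' @return An object of class `contact_map`: a list with elements `mat`,
#'   `bins`, `resolution`, `chrom`, `balanced`, `mask`.
#' @export
contact_map <- function(mat, bins, resolution, chrom,
                        balanced = FALSE, mask = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  n <- nrow(mat)
  validate_bins(bins, resolution, n)
  if (any(mat < 0)) stop("contact counts must be non-negative")
  if (sum(mat) <= 0) stop("total count > 0 violated")
  if (max(abs(mat - t(mat))) > 1e-8 * max(1, max(mat)))
    stop("contact matrix must be symmetric")
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(length(mask) == n)
  structure(
    list(mat = mat, bins = bins, resolution = as.numeric(resolution),
         chrom = as.character(chrom), balanced = isTRUE(balanced),
         mask = mask),
    class = "contact_map"
  )
}

validate_bins <- function(bins, resolution, n) {
  req <- c("chrom", "start", "end", "bin_id")
  if (!all(req %in% names(bins))) stop("bins must have columns ", paste(req, collapse = ", "))
  if (nrow(bins) != n) stop("bin table has ", nrow(bins), " rows but matrix has ", n)
  if (!identical(as.integer(bins$bin_id), 0:(n - 1L)))
    stop("bin_id must be dense 0..n-1 in order")
  if (any(diff(bins$start) <= 0)) stop("bins must be sorted and non-overlapping")
  w <- bins$end - bins$start
  if (n > 1 && any(w[-n] != resolution))
    stop("all bins except the last must have width = resolution")
  if (w[n] > resolution || w[n] <= 0) stop("last bin width must be in (0, resolution]")
  invisible(TRUE)
}

#' Build a regular bin table for one chromosome
#'
#' @param chrom chromosome name.
#' @param n_bins number of bins.
#' @param resolution bin width (bp).
#' @param chrom_length optional chromosome length; defaults to
#'   `n_bins * resolution` (the last bin is truncated when shorter).
#' @return data.frame of BED4-style bins with 0-based half-open coordinates.
#' @export
make_bins <- function(chrom, n_bins, resolution, chrom_length = NULL) {
  if (is.null(chrom_length)) chrom_length <- n_bins * resolution
  start <- (0:(n_bins - 1L)) * resolution
  end <- pmin(start + resolution, chrom_length)
  data.frame(chrom = chrom, start = start, end = end,
             bin_id = 0:(n_bins - 1L), stringsAsFactors = FALSE)
}

#' @export
print.contact_map <- function(x, ...) {
  n <- nrow(x$mat)
  cat(sprintf(
    "contact_map: %s, %d bins @ %g bp, total %.4g, %s, %d masked\n",
    x$chrom, n, x$resolution, sum(x$mat[upper.tri(x$mat, diag = TRUE)]),
    if (x$balanced) "balanced" else "raw", sum(x$mask)))
  invisible(x)
}

#' @export
as.matrix.contact_map <- function(x, ...) x$mat

#' Number of bins of a contact map
#' @param map a `contact_map`.
#' @return integer bin count.
#' @export
n_bins <- function(map) nrow(map$mat)

#' Read a contact map from COO triplets and a BED4 bin table
#'
#' The matrix file is whitespace/TAB-separated text with three columns
#' `bin_i bin_j count` (0-based bin ids).  Entries given in the lower
#' triangle are folded onto the upper triangle and duplicate `(i, j)` records
#' are summed, so a map written with both triangles reads back identical to
#' one written with the upper triangle only.
#'
#' @param matrix_path path to the 3-column triplet file.
#' @param bins_path path to the BED4 bin table (`chrom start end bin_id`).
#' @param chrom chromosome to load; bins of other chromosomes are an error
#'   (one chromosome per map).
#' @param balanced logical flag recorded on the returned map.
#' @return a [contact_map].
#' @export
read_contact_map <- function(matrix_path, bins_path, chrom, balanced = FALSE) {
  bins <- utils::read.table(bins_path, header = FALSE, sep = "",
                            col.names = c("chrom", "start", "end", "bin_id"),
                            stringsAsFactors = FALSE)
  bins <- bins[bins$chrom == chrom, , drop = FALSE]
  if (nrow(bins) == 0) stop("no bins for chromosome ", chrom)
  n <- nrow(bins)
  res <- bins$end[1] - bins$start[1]
  info <- file.info(matrix_path)
  trips <- if (!is.na(info$size) && info$size > 0)
    utils::read.table(matrix_path, header = FALSE, sep = "",
                      col.names = c("i", "j", "count"))
  else data.frame(i = integer(), j = integer(), count = numeric())
  if (nrow(trips) == 0) stop("total count > 0 violated (empty matrix file)")
  if (any(trips$count < 0)) stop("format error: negative count")
  if (any(trips$i < 0 | trips$i >= n | trips$j < 0 | trips$j >= n))
    stop("format error: bin index out of range [0, ", n - 1, "]")
  i <- pmin(trips$i, trips$j) + 1L
  j <- pmax(trips$i, trips$j) + 1L
  mat <- matrix(0, n, n)
  for (k in seq_along(i)) mat[i[k], j[k]] <- mat[i[k], j[k]] + trips$count[k]
  mat[lower.tri(mat)] <- t(mat)[lower.tri(mat)]
  contact_map(mat, bins, res, chrom, balanced = balanced)
}

#' Write a contact map as COO triplets and a BED4 bin table
#'
#' Writes the nonzero upper-triangle (including diagonal) entries.
#'
#' @param map a [contact_map].
#' @param matrix_path,bins_path output paths.
#' @return invisibly, the number of entries written.
#' @export
write_contact_map <- function(map, matrix_path, bins_path) {
  ut <- which(upper.tri(map$mat, diag = TRUE) & map$mat != 0, arr.ind = TRUE)
  df <- data.frame(i = ut[, 1] - 1L, j = ut[, 2] - 1L,
                   count = map$mat[ut])
  df <- df[order(df$i, df$j), ]
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(map$bins, bins_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(df))
}
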