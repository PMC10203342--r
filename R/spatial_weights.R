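#' k-nearest-neighbour row-standardized spatial weights
#'
#' Builds the sparse spatial weights matrix W used by the spatial lag
#' model: each pixel is linked to its k nearest neighbours by Euclidean
#' distance on the planar centroid coordinates, all neighbours equally
#' weighted, and rows standardized to sum to 1 (so each weight is 1/k).
#' Ties in distance (common on regular grids) are broken deterministically
#' by ascending pixel id. The matrix is generally asymmetric.
#'
#' Distances are computed in row blocks so no dense n x n matrix is ever
#' materialized.
#'
#' @param coords Two-column matrix or data frame of planar coordinates
#'   (metres), one row per pixel, in pixel-id order.
#' @param k Number of neighbours (default 8, a Moore neighbourhood on a
#'   square grid).
#' @param ids Optional integer ids used for tie-breaking; defaults to row
#'   order.
#' @return An object of class `spatial_weights`: a list with the sparse
#'   row-standardized matrix `W` (`dgCMatrix`), the neighbour index matrix
#'   `nb` (n x k), `n`, `k` and `row_standardized = TRUE`.
#' @export
#' @examples
#' xy <- expand.grid(x = 1:5, y = 1:5) * 1000
#' w <- knn_weights(xy, k = 8)
#' range(Matrix::rowSums(w$W))  # all rows sum to 1
knn_weights <- function(coords, k = 8, ids = NULL) {
  coords <- as.matrix(coords)[, 1:2, drop = FALSE]
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (!all(is.finite(coords))) abort("knn_weights: coordinates must be finite")
  if (n <= k) abort(sprintf("knn_weights: need n > k (n = %d, k = %d)", n, k))
  if (is.null(ids)) ids <- seq_len(n)

  nb <- matrix(0L, n, k)
  block <- max(1L, as.integer(2e6 / n))  # ~2e6 doubles per distance block
  x <- coords[, 1]
  y <- coords[, 2]
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    # squared distances from block rows to all points
    d2 <- outer(x[idx], x, "-")^2 + outer(y[idx], y, "-")^2
    for (j in seq_along(idx)) {
      i <- idx[j]
      d <- d2[j, ]
      d[i] <- Inf  # zero diagonal: a pixel is not its own neighbour
      ord <- order(d, ids)
      nb[i, ] <- ord[seq_len(k)]
    }
  }

  W <- sparseMatrix(i = rep(seq_len(n), each = k),
                    j = as.vector(t(nb)),
                    x = 1 / k, dims = c(n, n))
  structure(list(W = W, nb = nb, n = n, k = k, row_standardized = TRUE),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("# spatial_weights: %d pixels, k = %d nearest neighbours, row-standardized\n",
              x$n, x$k))
  invisible(x)
}

#' Export weights as a sparse triplet table
#'
#' @param w A `spatial_weights` object.
#' @return Tibble with columns `i`, `j`, `w` (1-based indices).
#' @export
weights_triplets <- function(w) {
  tr <- Matrix::summary(w$W)
  tibble::tibble(i = tr$i, j = tr$j, w = tr$x)
}

#' Global Moran's I with permutation inference
#'
#' I = (n / S0) * (z' W z) / (z' z) with z the mean-centred values and S0
#' the sum of all weights (equal to n for a row-standardized W). The
#' p-value is obtained by randomly permuting the values over the pixels;
#' the reported p is the two-one-sided permutation tail for positive
#' autocorrelation, Pr(I_perm >= I_obs), with the +1 correction.
#'
#' @param values Numeric vector, one value per pixel in weight order.
#' @param w A `spatial_weights` object.
#' @param n_permutations Number of random relabelings (default 199; 0
#'   skips inference).
#' @param seed Integer seed for the permutations.
#' @return Tibble with columns `statistic`, `expectation` (-1/(n-1)) and
#'   `p_value` (`NA` when `n_permutations = 0`).
#' @export
morans_i <- function(values, w, n_permutations = 199, seed = 1L) {
  n <- w$n
  stopifnot(length(values) == n)
  if (!all(is.finite(values))) abort("morans_i: values must be finite")
  if (sd(values) == 0) abort("morans_i: zero-variance values")
  z <- values - mean(values)
  s0 <- sum(w$W)
  stat_of <- function(z) (n / s0) * as.numeric(z %*% (w$W %*% z)) / sum(z^2)
  obs <- stat_of(z)
  p <- NA_real_
  if (n_permutations > 0) {
    set.seed(seed)
    perm <- vapply(seq_len(n_permutations),
                   function(i) stat_of(z[sample.int(n)]), numeric(1))
    p <- (sum(perm >= obs) + 1) / (n_permutations + 1)
  }
  tibble::tibble(statistic = obs, expectation = -1 / (n - 1), p_value = p)
}

# Restrict W to a pixel subset and re-standardize rows; rows left with no
# neighbour inside the subset become zero rows (isolated pixels).
restrict_weights <- function(w, keep) {
  Wsub <- w$W[keep, keep, drop = FALSE]
  rs <- Matrix::rowSums(Wsub)
  pos <- rs > 0
  if (any(pos)) {
    Wsub[pos, ] <- Wsub[pos, , drop = FALSE] / rs[pos]
  }
  structure(list(W = Wsub, nb = NULL, n = nrow(Wsub),
                 k = w$k, row_standardized = TRUE),
            class = "spatial_weights")
}
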