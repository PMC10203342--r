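# Brute-force oracles, independent of the implementation paths they check.

# nearest-water distance by exhaustive all-pairs search
oracle_distance_to_water <- function(mask, cell_size) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  wat <- which(mask, arr.ind = TRUE)
  out <- matrix(NA_real_, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      out[r, c] <- cell_size * sqrt(min((wat[, 1] - r)^2 + (wat[, 2] - c)^2))
    }
  }
  out
}

# exhaustive k-NN by full pairwise distances, ties by id ascending
oracle_knn <- function(coords, k) {
  n <- nrow(coords)
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- sqrt((coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2)
    d[i] <- Inf
    nb[i, ] <- order(d, seq_len(n))[seq_len(k)]
  }
  nb
}

# dense grid search of the concentrated SLM likelihood; dense determinants
oracle_slm_grid_search <- function(X, y, W_dense, rho_grid) {
  n <- length(y)
  ll <- vapply(rho_grid, function(rho) {
    A <- diag(n) - rho * W_dense
    ey <- as.numeric(A %*% y)
    b <- qr.solve(X, ey)
    e <- ey - as.numeric(X %*% b)
    s2 <- sum(e^2) / n
    -(n / 2) * log(2 * pi * s2) + determinant(A, logarithm = TRUE)$modulus - n / 2
  }, numeric(1))
  list(rho = rho_grid[which.max(ll)], ll = ll)
}

# beta at a fixed rho via dense normal equations
oracle_beta_at_rho <- function(X, y, W_dense, rho) {
  ey <- as.numeric((diag(length(y)) - rho * W_dense) %*% y)
  solve(crossprod(X), crossprod(X, ey))
}

# small default synthetic city shared across tests
tiny_city <- function(seed = 1, n = 16, ...) {
  synthetic_city(synthetic_config(n_rows = n, n_cols = n, seed = seed, ...))
}
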