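# Independent oracles, deliberately naive: used to cross-check the package's
# cost-distance and discretization code, never sharing its implementation.

# Brute-force shortest path on the water-cell adjacency graph by repeated
# relaxation (Bellman-Ford style) over an explicit edge list.
oracle_cost <- function(grid, src_row, src_col, neighborhood = 8) {
  nr <- grid$n_rows; nc <- grid$n_cols; cs <- grid$cell_size
  offs <- list(c(0, 1, 1), c(0, -1, 1), c(1, 0, 1), c(-1, 0, 1),
               c(1, 1, sqrt(2)), c(1, -1, sqrt(2)),
               c(-1, 1, sqrt(2)), c(-1, -1, sqrt(2)))
  if (neighborhood == 16) {
    for (d in list(c(1, 2), c(1, -2), c(-1, 2), c(-1, -2),
                   c(2, 1), c(2, -1), c(-2, 1), c(-2, -1)))
      offs <- c(offs, list(c(d, sqrt(5))))
  }
  dist <- matrix(Inf, nr, nc)
  dist[src_row, src_col] <- 0
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (!grid$water[r, cc] || !is.finite(dist[r, cc])) next
      for (o in offs) {
        rr <- r + o[1]; c2 <- cc + o[2]
        if (rr < 1 || rr > nr || c2 < 1 || c2 > nc) next
        if (!grid$water[rr, c2]) next
        cand <- dist[r, cc] + cs * o[3]
        if (cand < dist[rr, c2] - 1e-12) { dist[rr, c2] <- cand; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  dist[!grid$water] <- NA_real_
  dist
}

random_grid <- function(seed, max_dim = 20, p_land = 0.3, cell_size = 15) {
  set.seed(seed)
  nr <- sample(4:max_dim, 1); nc <- sample(4:max_dim, 1)
  water <- matrix(runif(nr * nc) > p_land, nr, nc)
  if (!any(water)) water[1, 1] <- TRUE
  estuary_grid(water, cell_size)
}

random_water_cell <- function(grid, seed) {
  set.seed(seed)
  wc <- which(grid$water, arr.ind = TRUE)
  wc[sample.int(nrow(wc), 1), ]
}

# constant-valued cost surface on a 1x1 water grid: a stub whose extracted
# cost at the (only) cell centre is exactly `d`
const_surface <- function(d, id = "s") {
  g <- estuary_grid(matrix(TRUE, 1, 1), cell_size = 15)
  structure(list(source_id = id, grid = g, cost = matrix(d, 1, 1)),
            class = "cost_surface")
}

# independent recomputation of the discharge-weighted WWTP score
# ("spreadsheet style"): written from the formula, not from the package code
oracle_wwtp_scores <- function(d, vol) {
  inv <- 1 / d
  norm <- function(x) if (diff(range(x)) == 0) rep(1, length(x))
          else (x - min(x)) / (max(x) - min(x))
  (1 + norm(inv)) * (1 + norm(vol))
}

# brute-force class counts by sorted-order counting
oracle_class_counts <- function(x, lower_q, upper_q) {
  thr <- quantile(x, c(lower_q, upper_q), type = 7, names = FALSE)
  c(low = sum(x < thr[1]),
    medium = sum(x >= thr[1] & x <= thr[2]),
    high = sum(x > thr[2]))
}

# quick small regression design for forest tests (no spatial machinery)
toy_design <- function(seed, n = 60, p_noise = 4, beta = c(1.5, -1),
                       noise_sd = 0.3) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * (2 + p_noise)), n))
  names(x) <- c("x1", "x2",
                if (p_noise > 0) paste0("z", seq_len(p_noise)))
  y <- beta[1] * x$x1 + beta[2] * x$x2 + rnorm(n, 0, noise_sd)
  list(x = x, y = y)
}
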