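# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Jacobi fixed-point solve of (D - alpha W) f = (1 - alpha) y:
# f <- D^-1 (alpha W f + (1 - alpha) y). Converges for alpha in (0,1).
jacobi_rank_oracle <- function(W, y, alpha, tol = 1e-14, max_iter = 50000) {
  d <- rowSums(W)
  f <- rep(0, length(y))
  for (i in seq_len(max_iter)) {
    f_new <- (alpha * drop(W %*% f) + (1 - alpha) * y) / d
    if (max(abs(f_new - f)) < tol) return(f_new)
    f <- f_new
  }
  f
}

# queue-based flood fill: keep >= t_low pixels whose component (over the
# >= t_low support) touches a >= t_high pixel
flood_fill_oracle <- function(map, t_low, t_high, connectivity = 8) {
  H <- nrow(map); W <- ncol(map)
  support <- map >= t_low
  visited <- matrix(FALSE, H, W)
  out <- matrix(0, H, W)
  nb <- if (connectivity == 8)
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  seeds <- which(map >= t_high & !visited, arr.ind = TRUE)
  if (nrow(seeds) == 0) return(out)
  queue <- seeds
  visited[seeds] <- TRUE
  while (nrow(queue) > 0) {
    p <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    out[p] <- 1
    for (k in seq_len(nrow(nb))) {
      q <- p + nb[k, , drop = FALSE]
      if (q[1] < 1 || q[1] > H || q[2] < 1 || q[2] > W) next
      if (!visited[q] && support[q]) {
        visited[q] <- TRUE
        queue <- rbind(queue, q)
      }
    }
  }
  out
}

# exhaustive 256-bin between-class-variance search, written independently
brute_otsu_oracle <- function(x, levels = 256) {
  bins <- pmin(floor(x * levels), levels - 1)
  best_t <- 0; best_v <- -1
  n <- length(x)
  for (k in 1:(levels - 1)) {
    lo <- bins < k
    w0 <- sum(lo) / n
    if (w0 == 0 || w0 == 1) next
    m0 <- mean((bins[lo] + 0.5) / levels)
    m1 <- mean((bins[!lo] + 0.5) / levels)
    v <- w0 * (1 - w0) * (m0 - m1)^2
    if (v > best_v) { best_v <- v; best_t <- k / levels }
  }
  best_t
}

# random connected undirected weighted graph on n nodes (tree + extra edges)
random_connected_graph <- function(n) {
  W <- matrix(0, n, n)
  for (i in 2:n) {
    j <- sample(i - 1, 1)
    W[i, j] <- W[j, i] <- runif(1, 0.1, 1)
  }
  extra <- max(0, round(n / 2))
  for (k in seq_len(extra)) {
    ij <- sample(n, 2)
    w <- runif(1, 0.1, 1)
    W[ij[1], ij[2]] <- W[ij[2], ij[1]] <- w
  }
  diag(W) <- 0
  W
}

graph_from_W <- function(W) {
  structure(list(W = W, D = diag(rowSums(W)), edges = W > 0, n = nrow(W)),
            class = "affinity_graph")
}

# small, fast fixture scene for saliency tests
disc_fixture <- function(seed = 7, size = 120, bg = "clutter") {
  generate_scene(scene_spec(
    size = c(size, size), object_shape = "disc", object_gray = 210,
    background = list(type = bg, gray = 70), noise_sigma = 5, seed = seed))
}
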