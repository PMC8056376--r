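# Independent oracles used across the suite. These deliberately use slow,
# literal formulations (double loops, recursive flood fill) so they stay
# independent of the package's vectorized/compiled implementations.

# Literal double-loop feature-similarity loss on a probability map:
# sum_n sum_i -delta(i - c_n) * ln(p_{n,i}).
oracleSimilarity <- function(prob, labels, eps = 1e-12) {
  d <- dim(prob)
  total <- 0
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    cn <- labels[r, c]
    for (i in seq_len(d[3]))
      if ((i - 1L) == cn) total <- total - log(prob[r, c, i] + eps)
  }
  total
}

# Literal continuity loss with the printed index bounds (both sums to W-1,
# H-1): xi indexes width (columns), eta height (rows).
oracleContinuity <- function(resp) {
  d <- dim(resp)
  H <- d[1]; W <- d[2]
  total <- 0
  for (xi in seq_len(W - 1)) for (eta in seq_len(H - 1)) {
    total <- total + sum(abs(resp[eta, xi + 1, ] - resp[eta, xi, ])) +
      sum(abs(resp[eta + 1, xi, ] - resp[eta, xi, ]))
  }
  total
}

# Per-pixel softmax, straightforward loop version.
oracleSoftmax <- function(resp) {
  d <- dim(resp)
  p <- array(0, d)
  for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
    e <- exp(resp[r, c, ] - max(resp[r, c, ]))
    p[r, c, ] <- e / sum(e)
  }
  p
}

# Queue-based flood fill component labeling (8- or 4-connected).
oracleFloodFill <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nb <- if (connectivity == 8L)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  k <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    k <- k + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- k
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (j in seq_len(nrow(nb))) {
        r <- p[1] + nb[j, 1]; c <- p[2] + nb[j, 2]
        if (r >= 1 && r <= H && c >= 1 && c <= W && mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- k
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Random response map with a fixed RNG stream.
randomResponses <- function(H, W, q) array(rnorm(H * W * q), c(H, W, q))

# A bright square on a dark background, the canonical two-region image.
twoRegionImage <- function(side = 32L, lo = 0.15, hi = 0.8) {
  img <- matrix(lo, side, side)
  a <- round(side * 0.3); b <- round(side * 0.75)
  img[a:b, a:b] <- hi
  img
}
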