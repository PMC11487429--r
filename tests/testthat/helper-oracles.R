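# Independent oracles used across the suite. These deliberately avoid the
# package's own implementation paths.

# O(n^2) all-pairs reference coincidence sorter with the same contract as
# the sliding-window sorter: a window opens at the earliest unconsumed
# single; membership decided by pairwise time differences; two members
# form a pair (kept iff the geometry acceptance passes), more are all
# discarded.
oracle_sort <- function(t, group, window, mode = "panel", n_groups = 4,
                        min_diff = 4) {
  n <- length(t)
  consumed <- rep(FALSE, n)
  pairs <- NULL
  for (i in seq_len(n)) {
    if (consumed[i]) next
    members <- i
    for (j in seq_len(n)) {
      if (j == i || consumed[j]) next
      if (t[j] >= t[i] && t[j] - t[i] <= window) members <- c(members, j)
    }
    members <- sort(members)
    consumed[members] <- TRUE
    if (length(members) == 2) {
      a <- members[1]; b <- members[2]
      ok <- if (mode == "panel") group[a] != group[b] else {
        d <- abs(group[a] - group[b])
        min(d, n_groups - d) >= min_diff
      }
      if (ok) pairs <- rbind(pairs, c(a, b))
    }
    if (length(members) == 1) consumed[i] <- TRUE
  }
  pairs
}

# direct-sum SSIM implementation (triple loop over window positions)
oracle_ssim <- function(x, y, data_range, window = 11, sigma = 1.5,
                        K1 = 0.01, K2 = 0.03) {
  r <- (window - 1) / 2
  k1d <- exp(-0.5 * ((-r:r) / sigma)^2)
  k1d <- k1d / sum(k1d)
  K <- outer(k1d, k1d)
  C1 <- (K1 * data_range)^2; C2 <- (K2 * data_range)^2
  vals <- c()
  for (i in (r + 1):(nrow(x) - r))
    for (j in (r + 1):(ncol(x) - r)) {
      wx <- x[(i - r):(i + r), (j - r):(j + r)]
      wy <- y[(i - r):(i + r), (j - r):(j + r)]
      mx <- sum(K * wx); my <- sum(K * wy)
      vx <- sum(K * wx^2) - mx^2; vy <- sum(K * wy^2) - my^2
      cxy <- sum(K * wx * wy) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                  ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  mean(vals)
}

# sample a synthetic Gaussian image on a grid
synth_gaussian <- function(grid, A, center, sigma, C = 0) {
  xs <- grid_centers(grid, 1); ys <- grid_centers(grid, 2)
  zs <- grid_centers(grid, 3)
  co <- expand.grid(x = xs, y = ys, z = zs)
  v <- A * exp(-((co$x - center[1])^2 / (2 * sigma[1]^2) +
                   (co$y - center[2])^2 / (2 * sigma[2]^2) +
                   (co$z - center[3])^2 / (2 * sigma[3]^2))) + C
  image_volume(array(v, grid$dim), grid)
}

# numeric Klein-Nishina mean scattering cosine at energy E (oracle for the
# sampled Compton kinematics), via simple quadrature over cos(theta)
kn_mean_cos <- function(ekeV) {
  a <- ekeV / 511
  ct <- seq(-1, 1, length.out = 20001)
  eps <- 1 / (1 + a * (1 - ct))
  dsdo <- eps^2 * (eps + 1 / eps - (1 - ct^2))
  sum(ct * dsdo) / sum(dsdo)
}

expect_rel <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected), tol * abs(expected))
}
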