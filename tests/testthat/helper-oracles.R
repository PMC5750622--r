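# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force expansion for weighted statistics,
# a queue-based flood fill for connectivity, direct ray checks for
# projections.

# Brute-force circular statistics on an unweighted angle sample.
rbar_oracle <- function(theta) {
  sqrt(mean(cos(theta))^2 + mean(sin(theta))^2)
}
dir_oracle <- function(theta) {
  atan2(mean(sin(theta)), mean(cos(theta))) %% (2 * pi)
}
u2_oracle <- function(theta) {
  u <- sort((theta %% (2 * pi)) / (2 * pi))
  n <- length(u)
  i <- seq_len(n)
  sum((u - (2 * i - 1) / (2 * n) - mean(u) + 0.5)^2) + 1 / (12 * n)
}

# Population moments of an expanded (unweighted) sample.
skew_oracle <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}
kurt_oracle <- function(x) {
  m <- mean(x)
  mean((x - m)^4) / mean((x - m)^2)^2 - 3
}

# Queue-based 8-connected flood fill; returns number of components.
flood_fill_n_components <- function(mask) {
  mask <- mask > 0
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0L
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (r0 in seq_len(nrow(mask))) for (c0 in seq_len(ncol(mask))) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    n <- n + 1L
    queue <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    while (length(queue) > 0) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs$dr[k]; cc <- p[2] + offs$dc[k]
        if (r >= 1 && r <= nrow(mask) && cc >= 1 && cc <= ncol(mask) &&
            mask[r, cc] && !seen[r, cc]) {
          seen[r, cc] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, cc)
        }
      }
    }
  }
  n
}

# Recall / precision of a detected mask against a truth mask at a
# 1-pixel (Chebyshev) tolerance.
mask_match <- function(det, truth) {
  grow <- function(m) {
    out <- m
    for (dr in -1:1) for (dc in -1:1) {
      sh <- matrix(0, nrow(m), ncol(m))
      rs <- seq_len(nrow(m)) - dr; cs <- seq_len(ncol(m)) - dc
      rok <- rs >= 1 & rs <= nrow(m); cok <- cs >= 1 & cs <= ncol(m)
      sh[rok, cok] <- m[rs[rok], cs[cok]]
      out <- pmax(out, sh)
    }
    out
  }
  c(recall = if (sum(truth) == 0) 1 else sum(truth * grow(det)) / sum(truth),
    precision = if (sum(det) == 0) 1 else sum(det * grow(truth)) / sum(det))
}

# Random integer-weighted angle set for oracle-equivalence checks.
random_weight_set <- function(n_max = 500, w_max = 5) {
  n <- sample.int(n_max - 1, 1) + 1
  weighted_angles(runif(n, 0, 2 * pi), sample.int(w_max, n, replace = TRUE))
}

# A small simulated system plus its rasterization, shared across tests.
quick_system <- function(seed = 1, day = 26, voxel = 0.5, ...) {
  p <- sim_params(seed = seed, ...)
  sys <- simulate_root_system(p, day)
  list(params = p, system = sys, voxels = rasterize(sys, voxel))
}
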