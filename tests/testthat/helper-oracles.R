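# Independent brute-force oracles used to pin down expected values.

# Mutual information computed directly from a joint count table by looping
# over cells (no shared code with histogram_mi's vectorised path).
oracle_mi_from_counts <- function(counts) {
  n <- sum(counts)
  pa <- rowSums(counts) / n
  pb <- colSums(counts) / n
  mi <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    p <- counts[i, j] / n
    if (p > 0) mi <- mi + p * log(p / (pa[i] * pb[j]))
  }
  mi
}

# Brute-force joint table by explicit pixel loops.
oracle_joint_counts <- function(a, b, bins) {
  counts <- matrix(0, bins, bins)
  for (i in seq_along(a)) {
    ia <- min(floor(a[i] * bins) + 1, bins)
    ib <- min(floor(b[i] * bins) + 1, bins)
    counts[ia, ib] <- counts[ia, ib] + 1
  }
  counts
}

# Direct (non-separable) 2-D Gaussian convolution with symmetric
# reflection, vectorised over kernel offsets.
oracle_gauss_conv <- function(x, sigma, fsize) {
  half <- fsize %/% 2
  g1 <- exp(-0.5 * ((-half:half) / sigma)^2)
  k2 <- outer(g1, g1) / sum(g1)^2
  H <- nrow(x); W <- ncol(x)
  refl <- function(i, n) {
    p <- 2 * n
    i <- ((i - 1) %% p + p) %% p
    ifelse(i < n, i + 1, p - i)
  }
  out <- matrix(0, H, W)
  for (a in -half:half) {
    ri <- refl(seq_len(H) + a, H)
    for (b in -half:half) {
      ci <- refl(seq_len(W) + b, W)
      out <- out + k2[a + half + 1, b + half + 1] * x[ri, ci]
    }
  }
  out
}

# Exact two-sided Mann-Whitney p-value by exhaustive enumeration of all
# choose(nx + ny, nx) rank assignments of the pooled sample (handles ties
# through average ranks of the pooled multiset).
oracle_mann_whitney <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled, ties.method = "average")
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  # two-sided: probability of a U at least as extreme (in distance from
  # the mean) as observed
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# Brute-force connected-component count (4-neighbour flood fill).
oracle_count_components <- function(mask) {
  mask <- mask > 0
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  n <- 0
  for (sy in seq_len(H)) for (sx in seq_len(W)) {
    if (!mask[sy, sx] || seen[sy, sx]) next
    n <- n + 1
    queue <- list(c(sy, sx)); seen[sy, sx] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= H && q[2] >= 1 && q[2] <= W &&
            mask[q[1], q[2]] && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  n
}

# Small phantom configuration reused across tests (fast to generate).
small_phantom_config <- function(seed = 1L, n_structures = 3L,
                                 artifact_rate = 0) {
  phantom_config(image_height = 96L, image_width = 128L,
                 n_structures = n_structures,
                 artifact_rate = artifact_rate, seed = seed)
}
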