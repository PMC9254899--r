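# shared fixtures: everything is generated in code at test time

cubic10 <- function() unit_cell(10, 10, 10, 90, 90, 90)

# random well-conditioned lattice as a g6 vector (built from a random
# basis so positive-definiteness is guaranteed)
random_g6 <- function() {
  repeat {
    B <- matrix(stats::rnorm(9, 0, 10), 3, 3)
    G <- B %*% t(B)
    if (min(diag(G)) > 4 && det(G) > 1) {
      g <- c(G[1, 1], G[2, 2], G[3, 3], 2 * G[2, 3], 2 * G[1, 3],
             2 * G[1, 2])
      class(g) <- "g6"
      return(g)
    }
  }
}

g6_metric <- function(g) {
  g <- unclass(g)
  matrix(c(g[1], g[6] / 2, g[5] / 2,
           g[6] / 2, g[2], g[4] / 2,
           g[5] / 2, g[4] / 2, g[3]), 3, 3)
}

g6_of_metric <- function(G) {
  g <- c(G[1, 1], G[2, 2], G[3, 3], 2 * G[2, 3], 2 * G[1, 3], 2 * G[1, 2])
  class(g) <- "g6"
  g
}

# random integer matrix with entries in {-1,0,1} and det +/- 1
random_unimodular <- function() {
  repeat {
    M <- matrix(sample(-1:1, 9, replace = TRUE), 3, 3)
    if (abs(det(M)) == 1) return(M)
  }
}

# all 3x3 integer matrices with entries in -span..span and det +/-1
unimodular_family <- function(span = 1L) {
  v <- seq.int(-span, span)
  grid <- as.matrix(expand.grid(v, v, v, v, v, v, v, v, v))
  dets <- grid[, 1] * (grid[, 5] * grid[, 9] - grid[, 6] * grid[, 8]) -
    grid[, 4] * (grid[, 2] * grid[, 9] - grid[, 3] * grid[, 8]) +
    grid[, 7] * (grid[, 2] * grid[, 6] - grid[, 3] * grid[, 5])
  grid[abs(dets) == 1, , drop = FALSE]
}

# minimum of a^2+b^2+c^2 = trace(M G t(M)) over a unimodular family;
# brute-force oracle, independent of the stepwise reduction
min_trace_oracle <- function(G, fam) {
  q <- function(cols) {
    X <- fam[, cols, drop = FALSE]
    rowSums((X %*% G) * X)
  }
  min(q(1:3) + q(4:6) + q(7:9))
}

# tiny merged set over explicit indices
toy_merged <- function(id, H, I, cell = cubic10(), laue = "-1",
                       sigma = 0.1) {
  reflection_set(id, cell, laue,
                 data.frame(h = H[, 1], k = H[, 2], l = H[, 3],
                            intensity = I, sigma = sigma),
                 merged = TRUE)
}

# merged set holding the first n ASU indices of a full sphere
sphere_subset <- function(id, cell, laue, d_min, idx, intensity = 1) {
  A <- enumerate_asu(cell, laue, d_min)
  A <- A[idx, , drop = FALSE]
  toy_merged(id, A, rep_len(intensity, nrow(A)), cell = cell, laue = laue)
}
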