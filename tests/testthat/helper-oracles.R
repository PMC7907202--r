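# Independent brute-force reference implementations used by the tests.
# These stay deliberately naive (explicit loops, no shared code with the
# package internals they check).

oracle_attraction <- function(nodes, neighbors, c1, c2) {
  out <- nodes
  for (i in seq_len(nrow(nodes))) {
    acc <- c(0, 0, 0)
    for (j in neighbors[[i]]) {
      d <- nodes[j, ] - nodes[i, ]
      len <- sqrt(sum(d^2))
      if (len == 0) next
      acc <- acc + c1 * d * len^2 + c2 * d / len
    }
    out[i, ] <- nodes[i, ] + acc
  }
  out
}

oracle_repulsion <- function(nodes, cr) {
  n <- nrow(nodes)
  out <- nodes
  for (i in seq_len(n)) {
    acc <- c(0, 0, 0)
    for (j in seq_len(n)) {
      if (j == i) next
      d <- nodes[i, ] - nodes[j, ]
      l2 <- sum(d^2)
      if (l2 == 0) next
      acc <- acc + d / l2
    }
    v <- nodes[i, ] + cr / (2 * n) * acc
    out[i, ] <- v / sqrt(sum(v^2))
  }
  out
}

# exhaustive triple-loop clique-code marginal counts at one radius
oracle_counts <- function(vox, mask, rho) {
  d <- dim(vox)
  counts <- rep(0, 7)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (mask[x, y, z] != 1L) next
    if (x - rho < 1 || x + rho > d[1] || y - rho < 1 || y + rho > d[2] ||
        z - rho < 1 || z + rho > d[3]) next
    ctr <- vox[x, y, z]
    beta <- sum(c(vox[x - rho, y, z], vox[x + rho, y, z],
                  vox[x, y - rho, z], vox[x, y + rho, z],
                  vox[x, y, z - rho], vox[x, y, z + rho]) > ctr)
    counts[beta + 1] <- counts[beta + 1] + 1
  }
  counts
}

# exhaustive per-voxel Gibbs-energy oracle (complete cliques at all radii)
oracle_energy <- function(vox, radii, potentials) {
  d <- dim(vox)
  out <- array(NA_real_, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    if (any(c(x, y, z) - max(radii) < 1) || any(c(x, y, z) + max(radii) > d))
      next
    e <- 0
    for (k in seq_along(radii)) {
      rho <- radii[k]
      beta <- sum(c(vox[x - rho, y, z], vox[x + rho, y, z],
                    vox[x, y - rho, z], vox[x, y + rho, z],
                    vox[x, y, z - rho], vox[x, y, z + rho]) > vox[x, y, z])
      e <- e + potentials[beta + 1, k]
    }
    out[x, y, z] <- e
  }
  out
}
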