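# shared fixture builders, all programmatic

# 2-D Gaussian plane: matrix [y, x] with value b + A * exp(...)
gauss_plane <- function(nx, ny, x0, y0, sx, sy = sx, A = 100, b = 0) {
  outer(seq_len(ny), seq_len(nx), function(y, x) {
    b + A * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2)))
  })
}

# 3-D Gaussian spot stack (separable), dims [y, x, z]
gauss_stack <- function(nx, ny, nz, x0, y0, z0, sxy, sz, mass = 1000, b = 0,
                        channel = "donor") {
  wx <- exp(-((seq_len(nx) - x0)^2) / (2 * sxy^2))
  wy <- exp(-((seq_len(ny) - y0)^2) / (2 * sxy^2))
  wz <- exp(-((seq_len(nz) - z0)^2) / (2 * sz^2))
  arr <- (wy %o% wx) %o% wz
  channel_stack(b + mass * arr / sum(arr), channel = channel)
}

# independent ring-count oracle: explicit 2-D coordinates, explicit distance
# computation, brute-force pair loops; matching via igraph when available
ring_xy <- function(n, diameter) {
  theta <- 2 * pi * (seq_len(n) - 1) / n
  cbind(x = diameter / 2 * cos(theta), y = diameter / 2 * sin(theta))
}

oracle_counts <- function(donors, fluor, n, diameter, radius, mode) {
  xy <- ring_xy(n, diameter)
  d <- as.matrix(stats::dist(xy))
  dn <- which(donors & fluor)
  ac <- which(!donors & fluor)
  if (length(dn) == 0 || length(ac) == 0) return(0L)
  if (mode == "pair_count") {
    cnt <- 0L
    for (u in dn) for (v in ac) if (d[u, v] <= radius) cnt <- cnt + 1L
    return(cnt)
  }
  if (mode == "donor_count") {
    cnt <- 0L
    for (u in dn) if (any(d[u, ac] <= radius)) cnt <- cnt + 1L
    return(cnt)
  }
  if (mode == "matching") {
    edges <- integer(0)
    for (u in seq_along(dn)) for (v in seq_along(ac)) {
      if (d[dn[u], ac[v]] <= radius) edges <- c(edges, u, length(dn) + v)
    }
    if (length(edges) == 0) return(0L)
    g <- igraph::make_empty_graph(length(dn) + length(ac), directed = FALSE)
    igraph::V(g)$type <- rep(c(FALSE, TRUE), c(length(dn), length(ac)))
    g <- igraph::add_edges(g, edges)
    return(igraph::max_bipartite_match(g)$matching_size)
  }
  stop("unknown mode")
}

# exhaustive enumeration of fixed-count labelings (full maturation):
# mean count over all C(n, g) donor arrangements, via the oracle
enumerate_ring_mean <- function(g, n, diameter, radius, mode) {
  if (g == 0 || g == n) return(0)
  sets <- utils::combn(n, g)
  means <- apply(sets, 2, function(s) {
    donors <- rep(FALSE, n); donors[s] <- TRUE
    oracle_counts(donors, rep(TRUE, n), n, diameter, radius, mode)
  })
  mean(means)
}
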