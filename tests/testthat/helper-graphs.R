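# Shared fixtures, built in code.

path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}

cycle_graph <- function(n) {
  a <- path_graph(n)
  a[1, n] <- a[n, 1] <- 1
  a
}

star_graph <- function(leaves) {
  n <- leaves + 1
  a <- matrix(0, n, n)
  a[1, 2:n] <- a[2:n, 1] <- 1   # node 1 = hub
  a
}

# Erdos-Renyi G(n, p), resampled until connected; optional positive weights.
rand_connected_graph <- function(n, p = 0.2, weighted = TRUE) {
  repeat {
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
    a <- a + t(a)
    g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
    if (igraph::components(g)$no == 1) break
  }
  w <- NULL
  if (weighted) {
    w <- matrix(0, n, n)
    idx <- which(upper.tri(a) & a == 1)
    w[idx] <- stats::runif(length(idx), 0.5, 2)
    w <- w + t(w)
  }
  list(a = a, w = w)
}

# Independent all-pairs shortest-path oracle (Floyd-Warshall).
floyd_warshall <- function(a, w = NULL) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a != 0] <- if (is.null(w)) 1 else w[a != 0]
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

# weighted 4-cycle 1-2-3-4-1 with w12=1, w23=2, w34=3, w41=4
weighted_square <- function() {
  a <- cycle_graph(4)
  w <- matrix(0, 4, 4)
  w[1, 2] <- 1; w[2, 3] <- 2; w[3, 4] <- 3; w[4, 1] <- 4
  w <- w + t(w)
  list(a = a, w = w)
}

# unit square: 4-cycle with Euclidean coordinates
unit_square <- function() {
  xy <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  list(a = cycle_graph(4), d = as.matrix(stats::dist(xy)), xy = xy)
}

# 4 nodes on a line at positions 0, 1, 10, 2 with edges A-B, B-D, D-C:
# greedy routing gets trapped for 2 of the 6 directed nonadjacent pairs
line_trap <- function() {
  pos <- c(0, 1, 10, 2)
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 3] <- a[3, 4] <- 1
  a <- a + t(a)
  list(a = a, d = abs(outer(pos, pos, "-")), pos = pos)
}

# all permutations of 1..n (rows)
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- combinat_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

expect_same_ptsp <- function(x, y, tol = 1e-9) {
  ok <- !is.na(x$path_count)
  expect_identical(x$path_count[ok], y$path_count[ok])
  expect_lt(max(abs(x$mean[ok] - y$mean[ok]) / pmax(1, abs(x$mean[ok]))), tol)
}
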