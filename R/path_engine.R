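## Topological / geometrical shortest-path engine.
##
## The expensive object here is the mean projection of ALL topological
## shortest paths (mean pTSP) per nonadjacent pair, obtained by depth-limited
## recursive enumeration; three scheduling variants (naive, brute-force,
## memoization+prioritization) must give identical statistics, and an
## independent BFS-DAG dynamic program serves as oracle.

as_adjacency <- function(adjacency) {
  if (inherits(adjacency, "npso_network")) adjacency <- adjacency$adjacency
  a <- Matrix::drop0(
    as(Matrix::Matrix(adjacency, sparse = TRUE) != 0, "CsparseMatrix") * 1)
  if (!Matrix::isSymmetric(a)) stop("adjacency matrix must be symmetric")
  if (any(Matrix::diag(a) != 0)) stop("self-loops are not allowed")
  a
}

graph_from_adj <- function(a, weights = NULL) {
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  if (!is.null(weights)) {
    el <- igraph::as_edgelist(g, names = FALSE)
    wv <- weights[cbind(el[, 1], el[, 2])]
    if (any(!is.finite(wv)) || any(wv <= 0)) {
      stop("edge weights must be positive and finite")
    }
    igraph::E(g)$weight <- wv
  }
  g
}

assert_connected <- function(g) {
  if (igraph::components(g)$no != 1) {
    stop("the graph must be connected (or reduced to its largest connected component)")
  }
}

# 0-based neighbor lists for the C++ kernel
adjlist0 <- function(a) {
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  lapply(igraph::as_adj_list(g, mode = "all"), function(v) as.integer(v) - 1L)
}

#' Topological shortest-path lengths
#'
#' All-pairs minimum hop counts of the unweighted network (per-source BFS),
#' with per-node eccentricity, the network diameter and the per-node mean
#' shortest-path length used by source prioritization.
#'
#' @param adjacency symmetric adjacency matrix (dense or sparse) or an
#'   `npso_network`.
#' @return object of class `tsp_lengths`: list with integer `hop` matrix,
#'   `ecc`, `diameter`, `mean_tsp`, `n`.
#' @export
tsp_lengths <- function(adjacency) {
  a <- as_adjacency(adjacency)
  g <- graph_from_adj(a)
  assert_connected(g)
  hop <- igraph::distances(g, algorithm = "unweighted")
  storage.mode(hop) <- "integer"
  dimnames(hop) <- NULL
  structure(list(hop = hop, ecc = apply(hop, 1, max),
                 diameter = max(hop),
                 mean_tsp = rowSums(hop) / (nrow(hop) - 1),
                 n = nrow(hop)),
            class = "tsp_lengths")
}

#' @export
print.tsp_lengths <- function(x, ...) {
  cat(sprintf("topological shortest paths: %d nodes, diameter %d, mean TSP %.3f\n",
              x$n, x$diameter, mean(x$mean_tsp)))
  invisible(x)
}

#' Geometrical (weighted) shortest-path lengths
#'
#' Weighted shortest-path distance matrix where edges carry geometrical
#' distances; the GSP between two nodes may use more hops than their
#' topological shortest path.
#'
#' @inheritParams tsp_lengths
#' @param weights symmetric matrix of positive finite edge weights (entries
#'   for non-edges are ignored).
#' @return symmetric numeric matrix of weighted shortest-path lengths.
#' @export
gsp_lengths <- function(adjacency, weights) {
  a <- as_adjacency(adjacency)
  g <- graph_from_adj(a, weights)
  assert_connected(g)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  dimnames(d) <- NULL
  d
}

#' Prioritize source nodes by decreasing mean shortest path
#'
#' Heuristic ordering that places nodes with many long shortest paths first,
#' maximizing the depth reduction achieved by memoization. Ties are broken by
#' ascending node index.
#'
#' @param tsp a [tsp_lengths()] object.
#' @return integer permutation of `1:n` (source processing order).
#' @export
prioritize <- function(tsp) {
  stopifnot(inherits(tsp, "tsp_lengths"))
  order(-tsp$mean_tsp, seq_len(tsp$n))
}

#' Per-source recursion depth schedule
#'
#' Assigns each source node its maximum recursion depth before enumeration.
#' Under the brute-force variant the depth of every node is its eccentricity
#' (order-independent). Under the memoization variant the i-th node in the
#' order only needs depth max over strictly later nodes of their hop
#' distance, because symmetric pairs already covered by earlier sources are
#' skipped; the last node gets depth 0.
#'
#' @param tsp a [tsp_lengths()] object.
#' @param order source processing order (default [prioritize()]).
#' @param variant `"memo"` or `"brute"`.
#' @return object of class `depth_schedule`: list with `order`, `depths`
#'   (aligned with `order`: `depths[i]` belongs to node `order[i]`),
#'   `variant`, `diameter` and the depth `profile` (data frame with `L`,
#'   `count`, `M_L`, the proportion of nodes at each recursion depth).
#' @export
depth_schedule <- function(tsp, order = prioritize(tsp),
                           variant = c("memo", "brute")) {
  stopifnot(inherits(tsp, "tsp_lengths"))
  variant <- match.arg(variant)
  n <- tsp$n
  if (length(order) != n || !setequal(order, seq_len(n))) {
    stop("'order' must be a permutation of 1:n")
  }
  if (variant == "brute") {
    depths <- tsp$ecc[order]
  } else {
    depths <- integer(n)
    for (i in seq_len(n - 1)) {
      depths[i] <- max(tsp$hop[order[i], order[(i + 1):n]])
    }
    depths[n] <- 0L
  }
  lev <- factor(depths, levels = 0:tsp$diameter)
  counts <- as.integer(table(lev))
  profile <- data.frame(L = 0:tsp$diameter, count = counts, M_L = counts / n)
  structure(list(order = order, depths = as.integer(depths), variant = variant,
                 diameter = tsp$diameter, profile = profile, n = n),
            class = "depth_schedule")
}

#' @export
print.depth_schedule <- function(x, ...) {
  cat(sprintf("depth schedule (%s): %d nodes, diameter %d, mean depth %.2f\n",
              x$variant, x$n, x$diameter, mean(x$depths)))
  invisible(x)
}

#' Predicted enumeration cost from a depth profile
#'
#' Evaluates the per-depth cost terms `M_L * k^L` of the enumeration
#' complexity `O(N * sum_{L=2}^{d} M_L k^L)`, where `k` is the average degree
#' and `M_L` the proportion of nodes with recursion depth `L`.
#'
#' @param schedule a [depth_schedule()] object.
#' @param k average node degree (>= 1).
#' @return list with data frame `terms` (`L`, `M_L`, `term = N * M_L * k^L`
#'   for `L = 2..d`) and scalar `total`.
#' @export
complexity_estimate <- function(schedule, k) {
  stopifnot(inherits(schedule, "depth_schedule"), k >= 1)
  prof <- schedule$profile
  prof <- prof[prof$L >= 2, , drop = FALSE]
  terms <- data.frame(L = prof$L, M_L = prof$M_L,
                      term = schedule$n * prof$M_L * k^prof$L)
  list(terms = terms, total = sum(terms$term))
}

ptsp_checkpoint_read <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  list(count = d$count, sum = d$sum, j = d$j)
}

ptsp_checkpoint_write <- function(path, j, count, sum) {
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  writeLines("j\tcount\tsum", con)
  if (length(j)) {
    writeLines(sprintf("%d\t%.17g\t%.17g", j, count, sum), con)
  }
  close(con)
  file.rename(tmp, path)
}

#' Mean projection of all topological shortest paths
#'
#' For every nonadjacent node pair, enumerates all topological shortest paths
#' and accumulates the geometrical length (sum of edge weights) of each,
#' yielding the exact path count and the mean projection (mean pTSP). Three
#' scheduling variants are provided and give identical results:
#' \describe{
#'   \item{`naive`}{one depth-limited recursion per node pair.}
#'   \item{`brute`}{one recursion per source at depth equal to its
#'     eccentricity, recording all targets at once.}
#'   \item{`memo`}{memoization + prioritization: sources are ordered by
#'     decreasing mean shortest path and each records only targets later in
#'     the order, at a correspondingly reduced depth.}
#' }
#' `dag_pruned = TRUE` restricts descent to the BFS shortest-path DAG; the
#' statistics are provably identical, only the traversal cost changes.
#' Per-source recursions are independent: results do not depend on the number
#' of workers or on execution order.
#'
#' @inheritParams gsp_lengths
#' @param variant `"memo"`, `"brute"` or `"naive"`.
#' @param schedule optional [depth_schedule()] consistent with `variant`
#'   (ignored for `"naive"`).
#' @param dag_pruned prune recursion to the shortest-path DAG (identical
#'   results, smaller recursion tree).
#' @param workers number of parallel worker processes for the per-source
#'   recursions (forked; falls back to serial where unsupported).
#' @param checkpoint_dir optional directory for atomic per-source checkpoint
#'   files; a resumed run reuses them and yields identical merged output.
#' @return object of class `ptsp_stats`: list with symmetric matrices
#'   `path_count`, `proj_sum`, `mean` (NA on the diagonal and for adjacent
#'   pairs), the `adjacency` pattern and the `variant` used.
#' @export
mean_ptsp <- function(adjacency, weights, variant = c("memo", "brute", "naive"),
                      schedule = NULL, dag_pruned = FALSE, workers = 1L,
                      checkpoint_dir = NULL) {
  variant <- match.arg(variant)
  a <- as_adjacency(adjacency)
  n <- nrow(a)
  tsp <- tsp_lengths(a)
  adj0 <- adjlist0(a)
  w <- as.matrix(weights)
  el <- which(as.matrix(a) != 0)
  if (any(!is.finite(w[el])) || any(w[el] <= 0)) {
    stop("edge weights must be positive and finite")
  }

  if (variant == "naive") {
    count <- sum_m <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        L <- tsp$hop[i, j]
        if (L < 2) next
        rec <- logical(n); rec[j] <- TRUE
        res <- ptsp_enumerate_source(adj0, w, tsp$hop[i, ], i - 1L, L, rec,
                                     dag_pruned)
        count[i, j] <- count[j, i] <- res$count[j]
        sum_m[i, j] <- sum_m[j, i] <- res$sum[j]
      }
    }
    return(ptsp_stats_build(count, sum_m, a, tsp, "naive"))
  }

  if (is.null(schedule)) {
    schedule <- depth_schedule(tsp, variant = variant)
  }
  if (schedule$variant != variant) stop("schedule variant mismatch")
  if (schedule$n != n) stop("schedule does not match the graph")
  ord <- schedule$order
  pos <- integer(n); pos[ord] <- seq_len(n)

  run_source <- function(i) {   # i = position in the order
    src <- ord[i]
    L <- schedule$depths[i]
    rec <- tsp$hop[src, ] >= 2L
    if (variant == "memo") rec <- rec & (pos > i)
    if (!is.null(checkpoint_dir)) {
      f <- file.path(checkpoint_dir, sprintf("source_%06d.tsv", src))
      if (file.exists(f)) return(ptsp_checkpoint_read(f))
    }
    res <- ptsp_enumerate_source(adj0, w, tsp$hop[src, ], src - 1L, L, rec,
                                 dag_pruned)
    j <- which(rec)
    out <- list(count = res$count[j], sum = res$sum[j], j = j)
    if (!is.null(checkpoint_dir)) {
      ptsp_checkpoint_write(f, out$j, out$count, out$sum)
    }
    out
  }

  workers <- max(1L, as.integer(workers))
  results <- if (workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(n), run_source, mc.cores = workers)
  } else {
    lapply(seq_len(n), run_source)
  }

  count <- sum_m <- matrix(0, n, n)
  for (i in seq_len(n)) {    # fixed merge order: deterministic regardless of dispatch
    src <- ord[i]
    res <- results[[i]]
    count[src, res$j] <- res$count
    sum_m[src, res$j] <- res$sum
  }
  if (variant == "memo") {
    count <- count + t(count)
    sum_m <- sum_m + t(sum_m)
  } else {
    # each unordered pair computed from both endpoints; keep one, verify match
    if (max(abs(count - t(count))) > 0 ||
        max(abs(sum_m - t(sum_m))) > 1e-9 * max(1, max(sum_m))) {
      stop("internal error: asymmetric brute-force accumulation")
    }
  }
  ptsp_stats_build(count, sum_m, a, tsp, variant)
}

ptsp_stats_build <- function(count, sum_m, a, tsp, variant) {
  n <- nrow(count)
  nonadj <- tsp$hop >= 2L
  if (any(count[nonadj] < 1)) {
    stop("coverage error: some nonadjacent pair has no recorded shortest path")
  }
  mean_m <- matrix(NA_real_, n, n)
  mean_m[nonadj] <- sum_m[nonadj] / count[nonadj]
  count[!nonadj] <- NA_real_
  sum_m[!nonadj] <- NA_real_
  structure(list(path_count = count, proj_sum = sum_m, mean = mean_m,
                 adjacency = a, hop = tsp$hop, variant = variant, n = n),
            class = "ptsp_stats")
}

#' @export
print.ptsp_stats <- function(x, ...) {
  np <- sum(x$hop >= 2L) / 2
  cat(sprintf(
    "mean pTSP (%s variant): %d nodes, %d nonadjacent pairs, mean of means %.4f\n",
    x$variant, x$n, np, mean(x$mean[upper.tri(x$mean)], na.rm = TRUE)))
  invisible(x)
}

#' Dynamic-programming oracle for the mean pTSP
#'
#' Independent verification route: per source, over the BFS shortest-path
#' DAG, `count(v) = sum over predecessors u of count(u)` and
#' `sum(v) = sum over u of (sum(u) + count(u) * w(u, v))`, processing nodes
#' in increasing hop order. Counts are exact (double-precision integers).
#'
#' @inheritParams gsp_lengths
#' @return a `ptsp_stats` object (variant `"dp"`).
#' @export
mean_ptsp_dp <- function(adjacency, weights) {
  a <- as_adjacency(adjacency)
  n <- nrow(a)
  tsp <- tsp_lengths(a)
  w <- as.matrix(weights)
  am <- as.matrix(a) != 0
  count <- sum_m <- matrix(0, n, n)
  for (s in seq_len(n)) {
    hop <- tsp$hop[s, ]
    cnt <- numeric(n); sm <- numeric(n)
    cnt[s] <- 1
    for (lev in seq_len(max(hop))) {
      for (v in which(hop == lev)) {
        pred <- which(am[, v] & hop == lev - 1L)
        cnt[v] <- sum(cnt[pred])
        sm[v] <- sum(sm[pred] + cnt[pred] * w[pred, v])
      }
    }
    count[s, ] <- cnt
    sum_m[s, ] <- sm
  }
  ptsp_stats_build(count, sum_m, a, tsp, "dp")
}

#' Memory-frugal depth statistics for large graphs
#'
#' Computes eccentricities, the prioritized order and the memoization depths
#' without materializing the full hop matrix, by running BFS from chunks of
#' sources. Intended for depth-profile analyses on graphs too large to
#' enumerate.
#'
#' @inheritParams tsp_lengths
#' @param chunk number of BFS sources processed per block.
#' @return list with `ecc`, `mean_tsp`, `order`, `memo_depths` (per node, in
#'   node index order), `diameter`, `mean_ecc`, `mean_memo`.
#' @export
depth_summary <- function(adjacency, chunk = 512L) {
  a <- as_adjacency(adjacency)
  g <- graph_from_adj(a)
  assert_connected(g)
  n <- nrow(a)
  ecc <- numeric(n); mts <- numeric(n)
  starts <- seq(1L, n, by = chunk)
  for (s0 in starts) {
    idx <- s0:min(s0 + chunk - 1L, n)
    d <- igraph::distances(g, v = idx, algorithm = "unweighted")
    ecc[idx] <- apply(d, 1, max)
    mts[idx] <- rowSums(d) / (n - 1)
  }
  ord <- order(-mts, seq_len(n))
  pos <- integer(n); pos[ord] <- seq_len(n)
  memo <- numeric(n)
  for (s0 in starts) {
    idx <- s0:min(s0 + chunk - 1L, n)
    d <- igraph::distances(g, v = idx, algorithm = "unweighted")
    for (k in seq_along(idx)) {
      v <- idx[k]
      later <- pos > pos[v]
      memo[v] <- if (any(later)) max(d[k, later]) else 0
    }
  }
  list(ecc = ecc, mean_tsp = mts, order = ord, memo_depths = memo,
       diameter = max(ecc), mean_ecc = mean(ecc), mean_memo = mean(memo))
}
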