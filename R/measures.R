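## Geometrical congruence and greedy navigability measures.

#' Index pairs of nonadjacent nodes
#'
#' @inheritParams tsp_lengths
#' @return two-column integer matrix of unordered nonadjacent pairs (i < j).
#' @export
nonadjacent_pairs <- function(adjacency) {
  a <- as.matrix(as_adjacency(adjacency))
  which(upper.tri(a) & a == 0, arr.ind = TRUE)
}

gc_band <- function(gc) {
  if (gc < 0.4) "negligible" else if (gc < 0.6) "low"
  else if (gc < 0.8) "medium" else "high"
}

#' Geometrical congruence (GC)
#'
#' Quantifies how closely the topological shortest paths of a network follow
#' a reference geometry:
#' \deqn{GC = \frac{2}{n(n-1) - 2e} \sum_{i<j,\ (i,j) \notin E}
#'       \frac{RD(i,j)}{\overline{pTSP}(i,j)}}
#' i.e. the mean, over nonadjacent node pairs, of the ratio between a
#' reference distance RD (the geodesic, the weighted shortest path, or any
#' pairwise dissimilarity) and the mean projection of all topological
#' shortest paths. With RD no larger than the mean pTSP (always true for the
#' geodesic under metric weights, and for the GSP) GC lies in (0, 1], with a
#' qualitative scale: negligible \[0, 0.4), low \[0.4, 0.6),
#' medium \[0.6, 0.8), high \[0.8, 1\].
#'
#' The report also carries a two-sided Mann-Whitney p-value comparing the
#' reference-distance and mean-pTSP distributions (the hard-congruence test).
#'
#' @param ptsp a [mean_ptsp()] result covering every nonadjacent pair.
#' @param rd symmetric matrix of reference distances (finite on nonadjacent
#'   pairs), e.g. the geodesic matrix or [gsp_lengths()].
#' @return object of class `congruence_report`: list with `gc`, `band`,
#'   per-pair `ratios`, `p_value` (hard congruence), `pairs`, `n`, `e`.
#' @export
geometrical_congruence <- function(ptsp, rd) {
  stopifnot(inherits(ptsp, "ptsp_stats"))
  rd <- as.matrix(rd)
  pairs <- which(upper.tri(ptsp$hop) & ptsp$hop >= 2L, arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    stop("undefined measure: the graph has no nonadjacent pairs (complete graph)")
  }
  mp <- ptsp$mean[pairs]
  rv <- rd[pairs]
  if (any(is.na(mp))) stop("coverage error: mean pTSP missing for some pair")
  if (any(!is.finite(rv))) stop("reference distance not finite on some nonadjacent pair")
  ratios <- rv / mp
  gc <- mean(ratios)
  structure(list(gc = gc, band = gc_band(gc), ratios = ratios,
                 p_value = hard_congruence_test(rv, mp),
                 pairs = pairs, n = ptsp$n,
                 e = as.integer(sum(ptsp$hop == 1L) / 2)),
            class = "congruence_report")
}

#' @export
print.congruence_report <- function(x, ...) {
  cat(sprintf("geometrical congruence: GC = %.4f (%s congruence)\n", x$gc, x$band))
  cat(sprintf("  %d nonadjacent pairs (n = %d, e = %d); hard-congruence Mann-Whitney p = %.3g\n",
              nrow(x$pairs), x$n, x$e, x$p_value))
  invisible(x)
}

#' Hard-congruence test (Mann-Whitney)
#'
#' Two-sided Mann-Whitney U test comparing the distribution of reference
#' distances (e.g. geodesics) with the distribution of mean pTSP values over
#' nonadjacent pairs. Hard congruence — statistical indistinguishability of
#' the two distributions — is rejected at p < 0.01. The test is exact for
#' combined sample sizes up to 20 and otherwise uses the normal approximation
#' with tie correction.
#'
#' @param x,y numeric samples (one value per nonadjacent pair).
#' @return two-sided p-value.
#' @export
hard_congruence_test <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  exact <- (length(x) + length(y)) <= 20
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value)
}

#' Simulate one greedy routing (myopic transfer) path
#'
#' From the source, repeatedly move to the neighbor closest to the
#' destination in the guide geometry (a node only sees its neighbors'
#' distances to the destination). The route succeeds on reaching the
#' destination and fails as soon as the chosen next node was already visited
#' on this route (with a deterministic memoryless rule, any revisit implies
#' an infinite loop; the packet "returning to the previously visited node" is
#' the common instance). Ties among equidistant neighbors go to the lowest
#' node index. A hard cap of n steps guards against degenerate input.
#'
#' @inheritParams tsp_lengths
#' @param guide symmetric matrix of node-pair distances steering the myopic
#'   choice (e.g. hyperbolic or Euclidean coordinates distances).
#' @param from,to source and destination node indices (`from != to`).
#' @param weights symmetric matrix of edge lengths used to measure the
#'   projection of the route (defaults to `guide`).
#' @return list with `success`, `path` (node indices), `hops`, and `pgrp`
#'   (geometrical length of the route; `Inf` when unsuccessful).
#' @export
greedy_route <- function(adjacency, guide, from, to, weights = NULL) {
  a <- as.matrix(as_adjacency(adjacency))
  guide <- as.matrix(guide)
  if (is.null(weights)) weights <- guide
  nbl <- apply(a != 0, 1, which, simplify = FALSE)
  route_one(nbl, guide, weights, from, to)
}

# inner loop over a prebuilt neighbor list
route_one <- function(nbl, guide, weights, from, to) {
  if (from == to) stop("'from' and 'to' must differ")
  n <- length(nbl)
  visited <- logical(n)
  cur <- from
  visited[cur] <- TRUE
  path <- cur
  len <- 0
  for (step in seq_len(n)) {
    nb <- nbl[[cur]]
    nxt <- nb[which.min(guide[nb, to])]   # which.min tie -> lowest index
    len <- len + weights[cur, nxt]
    path <- c(path, nxt)
    if (nxt == to) {
      return(list(success = TRUE, path = path, hops = length(path) - 1L,
                  pgrp = len))
    }
    if (visited[nxt]) {
      return(list(success = FALSE, path = path, hops = length(path) - 1L,
                  pgrp = Inf))
    }
    visited[nxt] <- TRUE
    cur <- nxt
  }
  list(success = FALSE, path = path, hops = length(path) - 1L, pgrp = Inf)
}

#' Greedy routing efficiency (GRE)
#'
#' Navigability score integrating success ratio and geometrical stretch:
#' \deqn{GRE = \frac{1}{n(n-1) - 2e} \sum_{(i,j)} \frac{RD(i,j)}{pGRP(i,j)}}
#' over directed nonadjacent pairs, where pGRP is the geometrical length of
#' the greedy routing path from i to j and is infinite (ratio 0) when the
#' route fails. An unsuccessful route scores 0, a successful route with
#' stretch scores in (0, 1), and a perfectly congruent route scores 1.
#' `include_adjacent = TRUE` switches to the legacy formulation averaging
#' over all n(n-1) ordered pairs.
#'
#' @inheritParams greedy_route
#' @param rd symmetric matrix of reference distances (e.g. geodesics or
#'   [gsp_lengths()]).
#' @param include_adjacent average over all ordered pairs instead of only
#'   nonadjacent ones.
#' @return list with `gre`, `success_ratio`, `n_pairs`, and a data frame
#'   `outcomes` (`from`, `to`, `success`, `pgrp`, `ratio`).
#' @export
greedy_routing_efficiency <- function(adjacency, guide, weights = NULL, rd,
                                      include_adjacent = FALSE) {
  a <- as.matrix(as_adjacency(adjacency))
  guide <- as.matrix(guide)
  if (is.null(weights)) weights <- guide
  rd <- as.matrix(rd)
  n <- nrow(a)
  sel <- if (include_adjacent) {
    which(!diag(TRUE, n), arr.ind = TRUE)
  } else {
    which(a == 0 & !diag(TRUE, n), arr.ind = TRUE)
  }
  if (nrow(sel) == 0) {
    stop("undefined measure: no nonadjacent pairs (complete graph)")
  }
  nbl <- apply(a != 0, 1, which, simplify = FALSE)
  np <- nrow(sel)
  succ <- logical(np); pgrp <- numeric(np); ratio <- numeric(np)
  for (k in seq_len(np)) {
    r <- route_one(nbl, guide, weights, sel[k, 1], sel[k, 2])
    succ[k] <- r$success
    pgrp[k] <- r$pgrp
    ratio[k] <- if (is.finite(r$pgrp)) rd[sel[k, 1], sel[k, 2]] / r$pgrp else 0
  }
  out <- data.frame(from = sel[, 1], to = sel[, 2], success = succ,
                    pgrp = pgrp, ratio = ratio)
  list(gre = sum(out$ratio) / np, success_ratio = mean(out$success),
       n_pairs = np, outcomes = out)
}

#' Edge betweenness weights
#'
#' Fallback dissimilarity for unweighted networks whose geometry is latent:
#' each edge is weighted by its unnormalized edge betweenness centrality
#' (number of shortest paths crossing it, split over multiplicities).
#'
#' @inheritParams tsp_lengths
#' @return symmetric matrix with positive EBC weights on edges, 0 elsewhere.
#' @export
ebc_weights <- function(adjacency) {
  a <- as_adjacency(adjacency)
  g <- graph_from_adj(a)
  assert_connected(g)
  eb <- igraph::edge_betweenness(g, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  n <- nrow(a)
  w <- matrix(0, n, n)
  w[el] <- eb
  w[el[, 2:1, drop = FALSE]] <- eb
  w
}
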