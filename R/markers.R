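## Connectome markers: GC and navigation efficiency (E_R) applied per subject
## to cohorts of weighted structural connectomes, with precision-recall
## evaluation and permutation trustworthiness.

#' Reverse streamline-count weights into distances
#'
#' Structural connectome weights (number of streamlines, NOS) express
#' connection strength; path-based measures need distance-like weights.
#' Regions joined by more streamlines are taken to be closer:
#' `w* = 1 / (1 + w)`, strictly decreasing, with `w* in (0, 1]`.
#'
#' @param w nonnegative finite weights (any shape).
#' @return reversed weights, same shape.
#' @export
reverse_weights <- function(w) {
  if (any(w < 0, na.rm = TRUE) || any(!is.finite(w[!is.na(w)]))) {
    stop("streamline-count weights must be nonnegative and finite")
  }
  1 / (1 + w)
}

#' Simulate a cohort of weighted connectomes with a planted group effect
#'
#' Generates `2 * n_per_group` subjects in two groups. Each subject's network
#' is an nPSO hyperbolic graph; the temperature of group B is shifted by
#' `effect_size` relative to group A, so `effect_size = 0` makes the groups
#' exchangeable while larger values plant a detectable topological/geometric
#' difference. Streamline-count-like weights are Poisson counts (plus one)
#' decaying with the subject's hyperbolic edge distances; 3D node centroids
#' come from one random embedding shared across subjects. At fixed seed the
#' cohort is reproduced byte-identically.
#'
#' @param n_per_group subjects per group (>= 2).
#' @param n_nodes nodes per subject network (>= 20, shared parcellation).
#' @param effect_size temperature shift of group B (keeps T < 1).
#' @param seed RNG seed.
#' @param m,base_temperature,gamma nPSO parameters of the group A condition.
#' @return object of class `connectome_cohort`: list with `weights` (list of
#'   symmetric count matrices), `group` (factor A/B), `centroids`
#'   (`n_nodes` x 3), `n_nodes`.
#' @export
synthetic_cohort <- function(n_per_group, n_nodes, effect_size = 0, seed = 1,
                             m = 3, base_temperature = 0.1, gamma = 2.5) {
  if (n_per_group < 2) stop("'n_per_group' must be >= 2")
  if (n_nodes < 20) stop("'n_nodes' must be >= 20")
  if (base_temperature + effect_size >= 1 || base_temperature + effect_size < 0) {
    stop("'effect_size' pushes the temperature outside [0, 1)")
  }
  set.seed(seed)
  centroids <- matrix(stats::rnorm(n_nodes * 3, sd = 40), n_nodes, 3)
  group <- factor(rep(c("A", "B"), each = n_per_group))
  temps <- ifelse(group == "B", base_temperature + effect_size,
                  base_temperature)
  weights <- vector("list", length(group))
  for (k in seq_along(group)) {
    sub_seed <- (seed * 1000L + k) %% .Machine$integer.max
    net <- npso(n_nodes, m, temperature = temps[k], gamma = gamma,
                communities = 0, seed = sub_seed, geo = TRUE)
    if (net$n < n_nodes) stop("subject network lost nodes to disconnection")
    am <- as.matrix(net$adjacency) != 0
    idx <- which(upper.tri(am) & am)
    gvals <- net$geo[idx]
    set.seed(sub_seed + 1L)
    counts <- stats::rpois(length(idx), lambda = 20 * exp(-gvals / mean(gvals))) + 1
    w <- matrix(0, n_nodes, n_nodes)
    w[idx] <- counts
    w <- w + t(w)
    weights[[k]] <- w
  }
  structure(list(weights = weights, group = group, centroids = centroids,
                 n_nodes = n_nodes,
                 params = list(n_per_group = n_per_group,
                               effect_size = effect_size, seed = seed, m = m,
                               base_temperature = base_temperature,
                               gamma = gamma)),
            class = "connectome_cohort")
}

#' @export
print.connectome_cohort <- function(x, ...) {
  cat(sprintf("connectome cohort: %d subjects (%s), %d nodes each\n",
              length(x$weights),
              paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                    collapse = ", "),
              x$n_nodes))
  invisible(x)
}

euclid_matrix <- function(xyz) {
  as.matrix(stats::dist(xyz))
}

#' Per-subject GC and navigation-efficiency markers
#'
#' For each subject, edges are weighted by distances — reversed streamline
#' counts (`mode = "nos"`) or Euclidean centroid distances (`mode = "3d"`) —
#' and two scalar markers are computed: GC(mean pTSP, GSP), the geometrical
#' congruence against the weighted shortest path in those distances, and
#' E_R, the greedy routing efficiency where the myopic choice is guided by
#' the Euclidean centroid geometry while path cost and reference distance use
#' the mode's edge distances. Subjects whose weighted graph is disconnected
#' are reduced to their largest connected component (with a message).
#'
#' @param cohort a [synthetic_cohort()] object, or any list with `weights`,
#'   `group` and `centroids` fields of the same shape.
#' @param mode `"nos"` (reversed streamline counts) or `"3d"` (Euclidean
#'   centroid distances).
#' @param markers which markers to compute (`"er"` needs centroids and
#'   dominates the runtime).
#' @return data frame of class `marker_table`: `subject`, `group`, `mode`,
#'   `gc`, `er` (NA when not requested).
#' @export
compute_markers <- function(cohort, mode = c("nos", "3d"),
                            markers = c("gc", "er")) {
  mode <- match.arg(mode)
  markers <- match.arg(markers, several.ok = TRUE)
  if (mode == "3d" && is.null(cohort$centroids)) {
    stop("mode '3d' requires node centroids")
  }
  if ("er" %in% markers && is.null(cohort$centroids)) {
    stop("navigation efficiency requires node centroids for the myopic guide")
  }
  euc <- if (!is.null(cohort$centroids)) euclid_matrix(cohort$centroids)
  ns <- length(cohort$weights)
  gc_v <- er_v <- rep(NA_real_, ns)
  for (k in seq_len(ns)) {
    w <- as.matrix(cohort$weights[[k]])
    adj <- (w > 0) * 1
    g <- igraph::graph_from_adjacency_matrix(Matrix::Matrix(adj, sparse = TRUE),
                                             mode = "undirected")
    comp <- igraph::components(g)
    keep <- seq_len(nrow(adj))
    if (comp$no > 1) {
      keep <- which(comp$membership == which.max(comp$csize))
      message(sprintf("subject %d: disconnected, keeping largest component (%d/%d nodes)",
                      k, length(keep), nrow(adj)))
      adj <- adj[keep, keep]; w <- w[keep, keep]
    }
    dist_m <- if (mode == "nos") {
      dm <- reverse_weights(w); dm[adj == 0] <- 0; dm
    } else {
      euc[keep, keep]
    }
    gsp <- gsp_lengths(adj, dist_m)
    if ("gc" %in% markers) {
      pt <- mean_ptsp(adj, dist_m, variant = "memo", dag_pruned = TRUE)
      gc_v[k] <- geometrical_congruence(pt, gsp)$gc
    }
    if ("er" %in% markers) {
      er_v[k] <- greedy_routing_efficiency(adj, guide = euc[keep, keep],
                                           weights = dist_m, rd = gsp)$gre
    }
  }
  out <- data.frame(subject = seq_len(ns), group = cohort$group, mode = mode,
                    gc = gc_v, er = er_v)
  class(out) <- c("marker_table", class(out))
  out
}

#' Area under the precision-recall curve
#'
#' Step-wise precision-recall integration over a descending-score threshold
#' sweep (tied scores enter as one block): AUPR = sum over thresholds of
#' (recall gain) x precision. Robust against unequal group sizes; a random
#' scorer scores about the prevalence of the positive class.
#'
#' @param scores numeric marker values (higher = more positive-like).
#' @param labels group labels, same length.
#' @param positive the label treated as positive class (default: the smaller
#'   group).
#' @return AUPR in \[0, 1\].
#' @export
auc_pr <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (is.null(positive)) {
    tb <- table(labels)
    positive <- names(tb)[which.min(tb)]
  }
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord] == positive
  s <- scores[ord]
  npos <- sum(y)
  tp <- cumsum(y)
  k <- seq_along(y)
  block_end <- c(s[-1] != s[-length(s)], TRUE)   # last index of each tie block
  prec <- tp[block_end] / k[block_end]
  rec <- tp[block_end] / npos
  sum(diff(c(0, rec)) * prec)
}

#' Permutation trustworthiness of an AUPR
#'
#' Assesses whether an observed AUPR exceeds chance by permuting the group
#' labels: `p = (1 + #[AUPR_perm >= AUPR_obs]) / (1 + B)`. For the four-marker
#' design (GC and E_R under two weightings) multiply by `markers` for a
#' Bonferroni-adjusted p-value.
#'
#' @inheritParams auc_pr
#' @param B number of permutations (>= 99).
#' @param seed RNG seed for reproducible permutations.
#' @param markers number of markers for Bonferroni adjustment (default 4).
#' @return list with `p_value`, `p_bonferroni` (capped at 1), `aupr`, `B`.
#' @export
aupr_trustworthiness <- function(scores, labels, B = 1000, seed = NULL,
                                 positive = NULL, markers = 4) {
  if (B < 99) stop("'B' must be >= 99")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(positive)) {
    tb <- table(as.character(labels))
    positive <- names(tb)[which.min(tb)]
  }
  obs <- auc_pr(scores, labels, positive)
  hits <- 0L
  for (b in seq_len(B)) {
    if (auc_pr(scores, sample(labels), positive) >= obs) hits <- hits + 1L
  }
  p <- (1 + hits) / (1 + B)
  list(p_value = p, p_bonferroni = min(1, p * markers), aupr = obs, B = B)
}
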