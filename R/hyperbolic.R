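#' Hyperbolic distance in the native disk
#'
#' Distance between two points of the hyperbolic plane (curvature -1) given in
#' native polar coordinates, as used by popularity-similarity network models:
#' \deqn{x = \mathrm{arccosh}(\cosh r_1 \cosh r_2 -
#'       \sinh r_1 \sinh r_2 \cos\Delta\theta)}
#' with \eqn{\Delta\theta = \pi - |\pi - |\theta_1 - \theta_2||} the angular
#' separation. All arguments are recycled, so whole coordinate vectors can be
#' evaluated at once.
#'
#' @param r1,r2 radial coordinates, must be >= 0.
#' @param theta1,theta2 angular coordinates (radians).
#' @return numeric vector of distances (>= 0).
#' @examples
#' hyperbolic_distance(1, 0, 1, pi)   # antipodal: r1 + r2 = 2
#' @export
hyperbolic_distance <- function(r1, theta1, r2, theta2) {
  if (any(r1 < 0) || any(r2 < 0)) {
    stop("radial coordinates must be non-negative")
  }
  dtheta <- pi - abs(pi - abs(theta1 - theta2) %% (2 * pi))
  arg <- cosh(r1) * cosh(r2) - sinh(r1) * sinh(r2) * cos(dtheta)
  # round-off can push the argument slightly below 1 for near-identical points
  acosh(pmax(arg, 1))
}

#' Sample angular coordinates (uniform or Gaussian mixture)
#'
#' Draws node angles on the circle. With `communities = 0` the angles are
#' i.i.d. uniform on \[0, 2pi) (classical PSO). With `communities = C >= 2`
#' they come from an equal-weight Gaussian mixture whose means are
#' equidistantly arranged over the angular space, mu_i = 2pi(i-1)/C, each with
#' standard deviation one sixth of the distance between adjacent means,
#' sigma = (1/6)(2pi/C); community membership of a node is the component whose
#' mean is circularly closest (ties broken toward the lower community index).
#'
#' @param communities number of mixture components C (0 = uniform, no
#'   communities; 1 is invalid).
#' @param n number of angles to draw.
#' @return list with `theta` (angles in \[0, 2pi)) and `community` (integer
#'   labels in 1..C, or `NULL` when `communities = 0`). Uses the current R RNG
#'   state; seed upstream for reproducibility.
#' @export
sample_angles <- function(communities, n) {
  stopifnot(n >= 1)
  if (communities == 1 || communities < 0) {
    stop("'communities' must be 0 (uniform) or an integer >= 2")
  }
  if (communities == 0) {
    return(list(theta = stats::runif(n, 0, 2 * pi), community = NULL))
  }
  C <- as.integer(communities)
  mu <- 2 * pi * (seq_len(C) - 1) / C
  sigma <- (1 / 6) * (2 * pi / C)
  comp <- sample.int(C, n, replace = TRUE)
  theta <- (stats::rnorm(n, mean = mu[comp], sd = sigma)) %% (2 * pi)
  # membership: circularly nearest mean, not the generating component
  dcirc <- outer(theta, mu, function(a, b) pi - abs(pi - abs(a - b) %% (2 * pi)))
  community <- apply(dcirc, 1, which.min)  # which.min ties -> lower index
  list(theta = theta, community = as.integer(community))
}

# Validate nPSO parameters; beta = 1/(gamma-1) derived.
npso_params <- function(n, m, temperature, gamma, communities, seed = NULL) {
  if (n < 2) stop("'n' must be >= 2")
  if (m < 1 || m >= n) stop("'m' must satisfy 1 <= m < n")
  if (temperature < 0 || temperature >= 1) stop("'temperature' must be in [0, 1)")
  if (gamma < 2) stop("'gamma' must be >= 2")
  if (communities == 1 || communities < 0) {
    stop("'communities' must be 0 or >= 2")
  }
  list(n = as.integer(n), m = as.integer(m), temperature = temperature,
       gamma = gamma, communities = as.integer(communities),
       beta = 1 / (gamma - 1), seed = seed)
}

# PSO cutoff radius R_t: chosen so the expected number of links of the new
# node t is m. Separate closed form for beta = 1 (gamma = 2).
pso_cutoff_radius <- function(t, m, temperature, beta) {
  rt <- 2 * log(t)
  if (abs(beta - 1) < 1e-12) {
    rt - 2 * log(2 * temperature * log(t) / (sin(pi * temperature) * m))
  } else {
    rt - 2 * log(2 * temperature * (1 - exp(-(1 - beta) * log(t))) /
                   (sin(pi * temperature) * m * (1 - beta)))
  }
}

#' Generate a (n)PSO hyperbolic network
#'
#' Grows a soft random geometric graph on the hyperbolic disk by
#' popularity-similarity optimization. Node t appears at radius r_t = 2 ln t
#' with an angular coordinate drawn by [sample_angles()]; earlier nodes drift
#' inward (popularity fading) to r_s(t) = beta 2 ln s + (1-beta) 2 ln t with
#' beta = 1/(gamma-1). Each new node links to m targets: at temperature T = 0
#' the m hyperbolically closest existing nodes; for T > 0, m distinct targets
#' sampled without replacement with probability proportional to
#' p(x) = 1 / (1 + exp((x - R_t) / (2T))), where R_t is the standard cutoff
#' radius making the expected number of new links equal m. When fewer than m
#' nodes exist, the new node connects to all of them, so the average degree is
#' close to (slightly below) 2m.
#'
#' The generator requires a connected result: it retries with fresh seeds up
#' to `max_retries` times and otherwise falls back to the largest connected
#' component with a warning.
#'
#' @param n number of nodes (>= 2).
#' @param m links added per new node (about half the target average degree).
#' @param temperature temperature T in \[0, 1); low T gives high clustering.
#' @param gamma target power-law exponent of the degree distribution (>= 2).
#' @param communities number of tailored communities C (0 = classical PSO).
#' @param seed RNG seed (integer) for a reproducible network; `NULL` uses the
#'   current RNG state.
#' @param geo logical; compute the full matrix of pairwise hyperbolic
#'   geodesics (O(n^2) memory — disable for large n).
#' @param max_retries connectivity retry budget.
#' @return object of class `npso_network`: a list with `n`, sparse symmetric
#'   `adjacency` (0/1 `dgCMatrix`), coordinates `r` and `theta`, integer
#'   `community` labels (or `NULL`), geodesic matrix `geo` (or `NULL`), and
#'   the resolved `params`.
#' @examples
#' net <- npso(60, 3, temperature = 0.1, gamma = 2.5, communities = 4, seed = 1)
#' net
#' @export
npso <- function(n, m, temperature = 0.1, gamma = 2.5, communities = 0,
                 seed = NULL, geo = TRUE, max_retries = 10) {
  params <- npso_params(n, m, temperature, gamma, communities, seed)
  for (attempt in 0:max_retries) {
    if (!is.null(seed)) set.seed(seed + attempt)
    net <- npso_grow_once(params)
    comp <- igraph::components(npso_igraph(net))
    if (comp$no == 1) {
      net$params$attempt <- attempt
      if (geo) net$geo <- npso_geo_matrix(net)
      return(net)
    }
  }
  keep <- which(comp$membership == which.max(comp$csize))
  if (length(keep) < 2) stop("could not grow a usable connected component")
  warning(sprintf(
    "network disconnected after %d retries; keeping largest component (%d of %d nodes)",
    max_retries, length(keep), params$n))
  net$adjacency <- net$adjacency[keep, keep, drop = FALSE]
  net$r <- net$r[keep]
  net$theta <- net$theta[keep]
  if (!is.null(net$community)) net$community <- net$community[keep]
  net$n <- length(keep)
  net$params$attempt <- max_retries
  if (geo) net$geo <- npso_geo_matrix(net)
  net
}

# One growth pass (no connectivity check). Draw order: all angles first, then
# per new node t = 2..n one call to sample() when T > 0.
npso_grow_once <- function(params) {
  n <- params$n; m <- params$m; temperature <- params$temperature
  beta <- params$beta
  ang <- sample_angles(params$communities, n)
  theta <- ang$theta
  log_s <- log(seq_len(n))
  edges_from <- vector("list", n)
  for (t in 2:n) {
    existing <- seq_len(t - 1)
    rs <- 2 * (beta * log_s[existing] + (1 - beta) * log_s[t])
    if (t - 1 <= m) {
      targets <- existing
    } else {
      x <- hyperbolic_distance(rs, theta[existing], 2 * log_s[t], theta[t])
      if (temperature == 0) {
        targets <- existing[order(x)[seq_len(m)]]
      } else {
        Rt <- pso_cutoff_radius(t, m, temperature, beta)
        p <- stats::plogis((Rt - x) / (2 * temperature))
        targets <- sample(existing, m, prob = pmax(p, 1e-300))
      }
    }
    edges_from[[t]] <- targets
  }
  ii <- rep.int(2:n, lengths(edges_from)[2:n])
  jj <- unlist(edges_from[2:n], use.names = FALSE)
  adjacency <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                                    dims = c(n, n))
  adjacency@x[] <- 1  # collapse any duplicates to simple 0/1
  r_final <- 2 * (beta * log_s + (1 - beta) * log_s[n])
  structure(list(n = n, adjacency = adjacency, r = r_final, theta = theta,
                 community = ang$community, geo = NULL, params = params),
            class = "npso_network")
}

npso_geo_matrix <- function(net) {
  n <- net$n
  dtheta <- outer(net$theta, net$theta, function(a, b)
    pi - abs(pi - abs(a - b) %% (2 * pi)))
  arg <- outer(cosh(net$r), cosh(net$r)) - outer(sinh(net$r), sinh(net$r)) * cos(dtheta)
  geo <- acosh(pmax(arg, 1))
  diag(geo) <- 0
  geo
}

npso_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' @export
print.npso_network <- function(x, ...) {
  e <- Matrix::nnzero(x$adjacency) / 2
  cat(sprintf("nPSO hyperbolic network: %d nodes, %d edges (mean degree %.2f)\n",
              x$n, e, 2 * e / x$n))
  p <- x$params
  cat(sprintf("  m = %d, T = %g, gamma = %g, C = %d%s\n", p$m, p$temperature,
              p$gamma, p$communities,
              if (!is.null(p$seed)) sprintf(", seed = %d", p$seed) else ""))
  if (!is.null(x$geo)) cat("  geodesic matrix: available\n")
  invisible(x)
}

#' @export
summary.npso_network <- function(object, ...) {
  g <- npso_igraph(object)
  deg <- igraph::degree(g)
  out <- list(n = object$n, edges = igraph::ecount(g),
              mean_degree = mean(deg), max_degree = max(deg),
              clustering = igraph::transitivity(g, type = "global"),
              communities = object$params$communities)
  class(out) <- "summary.npso_network"
  out
}

#' @export
print.summary.npso_network <- function(x, ...) {
  cat(sprintf(
    "nodes %d | edges %d | mean degree %.2f | max degree %d | transitivity %.3f\n",
    x$n, x$edges, x$mean_degree, x$max_degree, x$clustering))
  invisible(x)
}
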