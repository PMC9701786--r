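# nPSO generator: metric, angular sampling, growth rules, structural laws.

test_that("hyperbolic distance satisfies the native-disk metric identities", {
  expect_equal(hyperbolic_distance(1.3, 0.7, 1.3, 0.7), 0)
  # antipodal closed form: distance through the origin
  expect_equal(hyperbolic_distance(1, 0, 2, pi), 3, tolerance = 1e-12)
  # direct high-precision evaluation of the metric formula
  expect_equal(hyperbolic_distance(1, 0, 1, pi / 2), acosh(cosh(1)^2),
               tolerance = 1e-12)
  set.seed(1)
  r <- runif(50, 0, 12); th <- runif(50, 0, 2 * pi)
  x12 <- hyperbolic_distance(r[1:25], th[1:25], r[26:50], th[26:50])
  x21 <- hyperbolic_distance(r[26:50], th[26:50], r[1:25], th[1:25])
  expect_equal(x12, x21)
  expect_true(all(x12 >= 0))
  expect_error(hyperbolic_distance(-1, 0, 1, 0), "non-negative")
})

test_that("angular sampling is uniform without communities and mixture-based with them", {
  expect_error(sample_angles(1, 10), "communities")
  set.seed(11)
  u <- sample_angles(0, 10000)
  expect_null(u$community)
  expect_true(all(u$theta >= 0 & u$theta < 2 * pi))
  expect_gt(stats::ks.test(u$theta / (2 * pi), "punif")$p.value, 0.01)

  set.seed(12)
  s <- sample_angles(4, 20000)
  # equal mixing proportions
  expect_true(all(abs(as.vector(table(s$community)) / 20000 - 0.25) < 0.02))
  # membership = circularly nearest of the means {0, pi/2, pi, 3pi/2}
  mu <- 2 * pi * (0:3) / 4
  dc <- outer(s$theta, mu, function(a, b) pi - abs(pi - abs(a - b) %% (2 * pi)))
  expect_equal(s$community, apply(dc, 1, which.min))
  # sigma = pi/12: angular deviation from the assigned mean
  dev <- dc[cbind(seq_along(s$theta), s$community)]
  expect_equal(sqrt(mean(dev^2)), pi / 12, tolerance = 0.05)
  # C = 2: an angle near 0 belongs to community 1
  set.seed(13)
  s2 <- sample_angles(2, 5000)
  near0 <- pi - abs(pi - s2$theta) < pi / 4
  expect_true(all(s2$community[near0] == 1L))
})

test_that("nPSO growth saturates early nodes and hits the target average degree", {
  net <- npso(3, 2, temperature = 0.1, gamma = 2.5, seed = 4)
  expect_equal(Matrix::nnzero(net$adjacency), 6)  # complete triangle
  md <- sapply(1:10, function(s) {
    n <- npso(1000, 6, temperature = 0.1, gamma = 2.5, seed = s, geo = FALSE)
    Matrix::nnzero(n$adjacency) / n$n
  })
  expect_lt(abs(mean(md) - 12) / 12, 0.10)
  expect_error(npso(10, 20), "m")
  expect_error(npso(100, 4, temperature = 1.2), "temperature")
  expect_error(npso(100, 4, gamma = 1.5), "gamma")
  expect_error(npso(100, 4, communities = 1), "communities")
})

test_that("at T = 0 each new node links exactly to its m hyperbolically closest predecessors", {
  n <- 150; m <- 4; gamma <- 2.5; beta <- 1 / (gamma - 1)
  net <- npso(n, m, temperature = 0, gamma = gamma, seed = 21, geo = FALSE)
  expect_identical(net$n, 150L)  # connected at this seed, no component fallback
  a <- as.matrix(net$adjacency)
  for (t in c(20, 77, 150)) {
    chosen <- which(a[t, seq_len(t - 1)] != 0)
    # recompute coordinates as they stood when node t arrived
    rs <- 2 * (beta * log(seq_len(t - 1)) + (1 - beta) * log(t))
    x <- hyperbolic_distance(rs, net$theta[seq_len(t - 1)], 2 * log(t), net$theta[t])
    expect_setequal(chosen, order(x)[seq_len(m)])
  }
})

test_that("geodesic matrix is a metric consistent with the disk geometry", {
  net <- npso(80, 4, temperature = 0.1, gamma = 2.5, communities = 3, seed = 31)
  g <- net$geo
  expect_equal(g, t(g))
  expect_true(all(diag(g) == 0))
  expect_true(all(g[upper.tri(g)] > 0))
  # triangle inequality on sampled triples
  set.seed(31)
  tri <- replicate(300, sample(net$n, 3))
  viol <- apply(tri, 2, function(v) g[v[1], v[2]] > g[v[1], v[3]] + g[v[3], v[2]] + 1e-9)
  expect_false(any(viol))
  # upper bound via the disk origin
  expect_true(all(g <= outer(net$r, net$r, "+") + 1e-9))
})

test_that("clustering decreases with temperature", {
  trans <- sapply(c(0.1, 0.5, 0.9), function(Tv) {
    mean(sapply(1:10, function(s) {
      net <- npso(300, 4, temperature = Tv, gamma = 2.5, seed = 40 + s, geo = FALSE)
      igraph::transitivity(igraph::graph_from_adjacency_matrix(
        net$adjacency, mode = "undirected"), type = "global")
    }))
  })
  expect_gt(trans[1], trans[2])
  expect_gt(trans[2], trans[3])
})

test_that("tailored communities beat a degree-preserving null in modularity", {
  net <- npso(300, 4, temperature = 0.1, gamma = 2.5, communities = 4, seed = 51,
              geo = FALSE)
  expect_identical(net$n, 300L)
  g <- igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
  q_obs <- igraph::modularity(g, membership = net$community)
  set.seed(52)
  q_null <- mean(sapply(1:10, function(i) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = 20 * igraph::ecount(g)))
    igraph::modularity(gr, membership = net$community)
  }))
  expect_gt(q_obs, q_null)
})

test_that("degree-distribution tail recovers the target power-law exponent", {
  net <- npso(10000, 6, temperature = 0.1, gamma = 2.5, communities = 0,
              seed = 5, geo = FALSE)
  deg <- Matrix::rowSums(net$adjacency)
  alpha <- igraph::fit_power_law(deg, xmin = 30)$alpha
  expect_lt(abs(alpha - 2.5), 0.2)
})
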