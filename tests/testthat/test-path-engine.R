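# Shortest-path engine: hop/weighted distances, scheduling, enumeration.

test_that("topological shortest-path lengths match hand values and an independent oracle", {
  p4 <- path_graph(4)
  t4 <- tsp_lengths(p4)
  expect_equal(t4$hop[1, 4], 3L)
  expect_equal(t4$ecc, c(3, 2, 2, 3))
  expect_equal(t4$diameter, 3L)
  c4 <- tsp_lengths(cycle_graph(4))
  expect_equal(c4$hop[1, 3], 2L)
  expect_equal(c4$hop[2, 4], 2L)
  set.seed(101)
  g <- rand_connected_graph(20, 0.2, weighted = FALSE)
  expect_equal(tsp_lengths(g$a)$hop,
               matrix(as.integer(floyd_warshall(g$a)), 20, 20))
  disc <- matrix(0, 4, 4); disc[1, 2] <- disc[2, 1] <- 1
  expect_error(tsp_lengths(disc), "connected")
})

test_that("weighted shortest paths relax across light detours and match Floyd-Warshall", {
  ws <- weighted_square()
  d <- gsp_lengths(ws$a, ws$w)
  expect_equal(d[1, 3], 3)
  expect_equal(d[2, 4], 5)
  tri <- matrix(1, 3, 3) - diag(3)
  wt <- matrix(c(0, 1, 3, 1, 0, 1, 3, 1, 0), 3, 3)
  expect_equal(gsp_lengths(tri, wt)[1, 3], 2)
  set.seed(102)
  g <- rand_connected_graph(18, 0.25)
  expect_equal(gsp_lengths(g$a, g$w), floyd_warshall(g$a, g$w))
  bad <- g$w
  e1 <- which(g$a == 1, arr.ind = TRUE)[1, ]
  bad[e1[1], e1[2]] <- bad[e1[2], e1[1]] <- -1
  expect_error(gsp_lengths(g$a, bad), "positive")
})

test_that("prioritization orders nodes by decreasing mean shortest path with index tie-break", {
  expect_equal(prioritize(tsp_lengths(path_graph(4))), c(1, 4, 2, 3))
  expect_equal(prioritize(tsp_lengths(cycle_graph(6))), 1:6)  # vertex-transitive
  st <- star_graph(5)   # hub first in index but lowest mean: leaves precede it
  expect_equal(prioritize(tsp_lengths(st)), c(2:6, 1))
})

test_that("depth schedules: brute = eccentricity, memo shrinks toward zero for the last node", {
  t4 <- tsp_lengths(path_graph(4))
  ord <- prioritize(t4)
  expect_equal(depth_schedule(t4, ord, "brute")$depths, t4$ecc[ord])
  expect_equal(depth_schedule(t4, ord, "memo")$depths, c(3L, 2L, 1L, 0L))
  set.seed(103)
  g <- rand_connected_graph(6, 0.35, weighted = FALSE)
  tg <- tsp_lengths(g$a)
  perms <- combinat_perms(6)
  for (k in seq_len(nrow(perms))) {   # exhaustive over all 720 orders
    ordk <- perms[k, ]
    memo <- depth_schedule(tg, ordk, "memo")$depths
    brute <- depth_schedule(tg, ordk, "brute")$depths
    if (any(memo > brute)) fail(sprintf("memo depth exceeds brute for order %s",
                                        paste(ordk, collapse = ",")))
    if (memo[6] != 0L) fail("last node in a memo schedule must have depth 0")
  }
  succeed()
  prof <- depth_schedule(tg, variant = "memo")$profile
  expect_equal(sum(prof$M_L), 1)
  expect_error(depth_schedule(tg, order = c(1, 1, 2, 3, 4, 5, 6)), "permutation")
})

test_that("complexity estimate follows N * sum M_L k^L", {
  t4 <- tsp_lengths(path_graph(4))
  sch <- depth_schedule(t4, variant = "memo")  # depths 3,2,1,0 -> M_2 = M_3 = 1/4
  est <- complexity_estimate(sch, k = 2)
  expect_equal(est$total, 4 * (0.25 * 2^2 + 0.25 * 2^3))
  est2 <- complexity_estimate(sch, k = 4)
  expect_equal(est2$terms$term / est$terms$term, 2^est$terms$L)
  # degenerate profile: every node at the same depth
  c6 <- tsp_lengths(cycle_graph(6))
  schb <- depth_schedule(c6, variant = "brute")  # all depths = 3
  expect_equal(complexity_estimate(schb, k = 2)$total, 6 * 2^3)
})

test_that("mean pTSP reproduces hand-enumerated path projections", {
  ws <- weighted_square()
  pt <- mean_ptsp(ws$a, ws$w, variant = "memo")
  expect_equal(pt$path_count[1, 3], 2)   # two 2-hop routes, projections 3 and 7
  expect_equal(pt$mean[1, 3], 5)
  expect_equal(pt$mean[2, 4], 5)         # projections 3 and 7 likewise
  p4 <- path_graph(4)
  w4 <- matrix(0, 4, 4); w4[1, 2] <- 0.3; w4[2, 3] <- 1.1; w4[3, 4] <- 0.6
  w4 <- w4 + t(w4)
  pt4 <- mean_ptsp(p4, w4, variant = "brute")
  expect_equal(pt4$path_count[1, 3], 1)  # unique shortest path
  expect_equal(pt4$mean[1, 3], 0.3 + 1.1)
  expect_equal(pt4$mean[1, 4], 0.3 + 1.1 + 0.6)
  us <- unit_square()
  dp <- mean_ptsp_dp(us$a, us$d)
  expect_equal(dp$path_count[1, 3], 2)
  expect_equal(dp$mean[1, 3], 2)
  # complete bipartite K_{2,3}: same-side pairs counted by the opposite side
  k23 <- matrix(0, 5, 5); k23[1:2, 3:5] <- 1; k23 <- k23 + t(k23)
  wk <- k23 * 0.7
  dpk <- mean_ptsp_dp(k23, wk)
  expect_equal(dpk$path_count[1, 2], 3)
  expect_equal(dpk$path_count[3, 4], 2)
  expect_equal(dpk$mean[1, 2], 1.4)
})

test_that("all enumeration variants agree with the DP oracle and respect depth dominance", {
  set.seed(104)
  for (rep in 1:20) {
    g <- rand_connected_graph(sample(8:30, 1), 0.18)
    tg <- tsp_lengths(g$a)
    memo <- mean_ptsp(g$a, g$w, "memo")
    for (alt in list(mean_ptsp(g$a, g$w, "brute"),
                     mean_ptsp(g$a, g$w, "naive"),
                     mean_ptsp(g$a, g$w, "memo", dag_pruned = TRUE),
                     mean_ptsp_dp(g$a, g$w))) {
      expect_same_ptsp(memo, alt)
    }
    ordr <- sample(tg$n)
    expect_lte(sum(depth_schedule(tg, ordr, "memo")$depths),
               sum(depth_schedule(tg, ordr, "brute")$depths))
    # mean projection can never undercut the weighted shortest path
    gsp <- gsp_lengths(g$a, g$w)
    ok <- !is.na(memo$mean)
    expect_true(all(memo$mean[ok] >= gsp[ok] - 1e-12))
  }
})

test_that("memo recording covers each nonadjacent pair exactly once", {
  set.seed(105)
  g <- rand_connected_graph(25, 0.15, weighted = FALSE)
  tg <- tsp_lengths(g$a)
  ord <- prioritize(tg)
  pos <- integer(tg$n); pos[ord] <- seq_len(tg$n)
  rec <- matrix(0L, tg$n, tg$n)
  for (i in seq_len(tg$n)) {
    src <- ord[i]
    j <- which(tg$hop[src, ] >= 2L & pos > i)
    rec[cbind(pmin(src, j), pmax(src, j))] <- rec[cbind(pmin(src, j), pmax(src, j))] + 1L
  }
  nonadj <- which(upper.tri(tg$hop) & tg$hop >= 2L)
  expect_true(all(rec[nonadj] == 1L))
  expect_true(all(rec[-nonadj] == 0L))
})

test_that("per-source recursions are worker-invariant and checkpoint-resumable", {
  set.seed(106)
  g <- rand_connected_graph(22, 0.2)
  p1 <- mean_ptsp(g$a, g$w, "memo", workers = 1)
  p2 <- mean_ptsp(g$a, g$w, "memo", workers = 2)
  p8 <- mean_ptsp(g$a, g$w, "memo", workers = 8)
  expect_identical(p1$path_count, p2$path_count)
  expect_identical(p1$proj_sum, p2$proj_sum)
  expect_identical(p1$proj_sum, p8$proj_sum)
  # interrupted run: half the checkpoints already on disk, rest recomputed
  ckdir <- withr::local_tempdir()
  full <- mean_ptsp(g$a, g$w, "memo", checkpoint_dir = ckdir)
  files <- list.files(ckdir, full.names = TRUE)
  file.remove(sample(files, length(files) %/% 2))
  resumed <- mean_ptsp(g$a, g$w, "memo", checkpoint_dir = ckdir)
  expect_equal(resumed$proj_sum, full$proj_sum, tolerance = 1e-15)
  expect_identical(resumed$path_count, full$path_count)
})

test_that("schedule/graph mismatches are rejected", {
  g <- path_graph(5)
  tg <- tsp_lengths(g)
  sch <- depth_schedule(tg, variant = "brute")
  w <- g * 1
  expect_error(mean_ptsp(g, w, "memo", schedule = sch), "mismatch")
  g2 <- path_graph(6)
  sch6 <- depth_schedule(tsp_lengths(g2), variant = "memo")
  expect_error(mean_ptsp(g, w, "memo", schedule = sch6), "match")
})
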