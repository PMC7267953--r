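coords4 <- gen_coords(8, 42, "uniform_box")
D4 <- dist_from_coords(coords4)

test_that("navigation sets follow the strict-inequality definition", {
  # collinear points 0,1,2 on a line (1-based: nodes 1,2,3): from u=1 via
  # v=2, both v and the far node are strictly closer to v
  coords <- cbind(c(0, 1, 2), 0, 0) + matrix(rnorm(9, sd = 1e-9), 3, 3)
  D <- dist_from_coords(coords)
  expect_setequal(navigation_set(1, 2, D), c(2, 3))
  # v farther from every node than u is: members = {v} only
  coords2 <- rbind(c(0, 0, 0), c(100, 0, 0), c(1, 1, 0), c(2, 0, 1))
  D2 <- dist_from_coords(coords2)
  expect_identical(navigation_set(1, 2, D2), 2L)
  expect_error(navigation_set(3, 3, D2), "differ")
  # union over v of S_v^u covers everything except u (w is in S_w^u)
  for (u in 1:nrow(D4)) {
    un <- sort(unique(unlist(lapply(setdiff(1:nrow(D4), u),
                                    function(v) navigation_set(u, v, D4)))))
    expect_identical(un, setdiff(1:nrow(D4), u))
  }
})

test_that("optimal navigation vectors are exact minimum covers", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    D <- dist_from_coords(gen_coords(n, 100 + rep, "uniform_box"))
    for (u in seq_len(n)) {
      others <- setdiff(seq_len(n), u)
      sets <- lapply(others, function(v) navigation_set(u, v, D))
      nb <- optimal_navigation_vector(u, D)
      expect_identical(length(nb), brute_min_cover_size(sets, others))
      expect_setequal(union(unlist(sets[match(nb, others)]), u), seq_len(n))
    }
  }
  # n = 2: the single other node is chosen
  Dp <- dist_from_coords(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_identical(optimal_navigation_vector(1, Dp), 2L)
})

test_that("the equilibrium network is navigable, symmetric, deterministic", {
  g <- build_nng(D4)
  expect_identical(g$adjacency, t(g$adjacency))
  expect_identical(diag(g$adjacency), rep(0L, nrow(D4)))
  expect_identical(g$M, sum(g$adjacency[upper.tri(g$adjacency)]))
  # adjacency is the symmetrized union of the chosen sets
  adj2 <- matrix(0L, nrow(D4), nrow(D4))
  for (u in seq_along(g$chosen)) {
    adj2[u, g$chosen[[u]]] <- 1L
    adj2[g$chosen[[u]], u] <- 1L
  }
  expect_identical(g$adjacency, adj2)
  expect_identical(build_nng(D4)$adjacency, g$adjacency)
  expect_equal(navigability(g$adjacency, D4), 1)
  # regular tetrahedron: all pairs equidistant, fully symmetric game
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  gt <- build_nng(dist_from_coords(tet))
  expect_equal(navigability(gt$adjacency, dist_from_coords(tet)), 1)
  # n = 2: a single edge
  Dp <- dist_from_coords(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_identical(build_nng(Dp)$M, 1L)
  # duplicate points rejected
  Ddup <- dist_from_coords(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                                 c(0, 1, 0)))
  expect_error(build_nng(Ddup), "positive")
})

test_that("greedy routing makes strict progress and succeeds on the NNG", {
  g <- build_nng(D4)
  n <- nrow(D4)
  # direct edge: two-hop path
  e <- unname(which(g$adjacency > 0, arr.ind = TRUE)[1, ])
  expect_identical(greedy_route(g$adjacency, D4, e[1], e[2]), e)
  # empty adjacency: failure
  expect_null(greedy_route(matrix(0, n, n), D4, 1, 2))
  expect_error(greedy_route(g$adjacency, D4, 2, 2), "differ")
  # every ordered pair is routable on the equilibrium network, and each
  # path makes strictly decreasing distance-to-target progress
  for (s in 1:n) for (t in 1:n) {
    if (s == t) next
    p <- greedy_route(g$adjacency, D4, s, t)
    expect_false(is.null(p))
    expect_identical(p[length(p)], t)
    expect_true(all(diff(D4[p, t]) < 0))
  }
})

test_that("navigability counts ordered pairs with an isolated node", {
  coords <- gen_coords(4, 9, "uniform_box")
  D <- dist_from_coords(coords)
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- adj[1, 3] <- adj[3, 1] <- 1
  # node 4 isolated: no ordered pair involving it can route; at most 6/12
  expect_lte(navigability(adj, D), 6 / 12)
  # complete graph: direct hop always possible
  expect_equal(navigability(matrix(1, 4, 4) - diag(4), D), 1)
})

test_that("edge classification satisfies |T| + |F| = |M|", {
  g <- build_nng(D4)
  n <- nrow(D4)
  # S identical to the NNG: optimality 1, no false positives
  S <- g$adjacency * 0.5
  cls <- classify_edges(S, g)
  expect_equal(cls$optimality, 1)
  expect_identical(cls$F_count, 0L)
  expect_identical(cls$T_count + cls$F_count, cls$M_count)
  # empty structural network: optimality 0, |F| = |M|
  cls0 <- classify_edges(matrix(0, n, n), g)
  expect_equal(cls0$optimality, 0)
  expect_identical(cls0$F_count, cls0$M_count)
  # S = NNG plus 5 extra edges: optimality 1, nonoptimal count 5
  S5 <- g$adjacency * 0.7
  free <- which(upper.tri(S5) & S5 == 0)
  add <- free[1:5]
  S5[add] <- 0.3
  S5 <- pmax(S5, t(S5))
  cls5 <- classify_edges(S5, g)
  expect_equal(cls5$optimality, 1)
  expect_identical(cls5$nonoptimal_count, 5L)
  expect_error(classify_edges(matrix(0, 3, 3), g), "mismatch")
})

test_that("per-block construction equals independent per-block games", {
  coords <- gen_coords(24, 77, "two_blobs")
  D <- dist_from_coords(coords)
  blocks <- rep(c("L", "R"), each = 12)
  # restrict distances block-diagonally by building per block
  g_all <- build_nng(D, blocks = blocks)
  gL <- build_nng(D[1:12, 1:12])
  gR <- build_nng(D[13:24, 13:24])
  expect_identical(g_all$adjacency[1:12, 1:12], gL$adjacency)
  expect_identical(g_all$adjacency[13:24, 13:24], gR$adjacency)
  expect_true(all(g_all$adjacency[1:12, 13:24] == 0))
  expect_identical(g_all$M, gL$M + gR$M)
})
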