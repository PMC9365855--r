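test_that("strength sums incident edge weights", {
  parc <- toy_parcellation(2)  # 4 regions; use first 3 for the toy graph
  net <- toy_network(parc, list(c(1, 2, 0.2), c(1, 3, 0.3), c(3, 4, 1)))
  s <- strength(net, parc)$values
  expect_equal(s[1:3], c(0.5, 0.2, 1.3))
  net2 <- net; net2$weights <- 2 * net2$weights
  expect_equal(strength(net2, parc)$values, 2 * s)
  k4 <- toy_network(parc, apply(utils::combn(4, 2), 2,
                                function(e) c(e, 1), simplify = FALSE))
  expect_equal(strength(k4, parc)$values, rep(3, 4))
})

test_that("betweenness and closeness reproduce hand-enumerated paths", {
  # path A - B - C with unit weights on a 4-region parcellation + spur
  parc <- toy_parcellation(2)
  path3 <- toy_network(parc, list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1)))
  b <- betweenness(path3, parc)$values
  # middle nodes of the 4-path: node 2 mediates pairs (1,3),(1,4); node 3
  # mediates (1,4),(2,4); ordered pairs double the counts, norm (n-1)(n-2)
  expect_equal(b, c(0, 4 / 6, 4 / 6, 0))
  cl <- closeness(path3, parc)$values
  expect_equal(cl, c(2, 4 / 3, 4 / 3, 2))

  # K3: no intermediates, all closeness 1
  k3parc <- toy_parcellation(2)
  k3 <- toy_network(k3parc, list(c(1, 2, 1), c(1, 3, 1), c(2, 3, 1),
                                 c(3, 4, 1), c(1, 4, 1), c(2, 4, 1)))
  expect_equal(betweenness(k3, k3parc)$values, rep(0, 4))
  expect_equal(closeness(k3, k3parc)$values, rep(1, 4))

  # weight scaling scales closeness by 1/c
  sc <- path3; sc$weights <- 4 * sc$weights
  expect_equal(closeness(sc, parc)$values, cl / 4)

  disconnected <- toy_network(parc, list(c(1, 2, 1), c(3, 4, 1)))
  expect_error(betweenness(disconnected, parc), "components")
  expect_error(closeness(disconnected, parc), "components")
})

test_that("path metrics match the brute-force enumeration oracle", {
  parc <- toy_parcellation(4)  # 8 regions
  for (s in 1:12) {
    net <- random_connected_network(parc, density = 0.45, seed = s)
    oracle <- brute_force_paths(net$weights)
    expect_equal(betweenness(net, parc)$values, oracle$betweenness,
                 tolerance = 1e-10, info = paste("seed", s))
    expect_equal(closeness(net, parc)$values, oracle$closeness,
                 tolerance = 1e-10, info = paste("seed", s))
  }
})

test_that("mean Euclidean distance follows the geometry", {
  parc3 <- parcellation(c("a", "b", "c", "d"), c("L", "L", "R", "R"),
                        rbind(c(-2, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(1, 0, 0)),
                        sphere_xyz = rbind(c(-1, 0, 0), c(-1, 0, 0),
                                           c(0, 1, 0), c(1, 0, 0)))
  # collinear triple 0,1,2 check on regions a,b,d (x = -2,-1,1): use direct
  d <- mean_euclidean_distance(parc3)$values
  dm <- centroid_distances(parc3)
  expect_equal(d, unname(rowSums(dm)) / 3)

  # rigid rotation leaves the values unchanged
  th <- 0.7
  rot <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  parc_rot <- parcellation(parc3$region_labels, parc3$hemisphere,
                           parc3$centroid_xyz %*% t(rot),
                           sphere_xyz = parc3$sphere_xyz)
  expect_equal(mean_euclidean_distance(parc_rot)$values, d,
               tolerance = 1e-10)

  # equilateral triangle side 1: all values 1 (hand geometry)
  tri <- rbind(c(-0.5, 0, 0), c(0.5, 0, 0), c(0, sqrt(3) / 2, 0),
               c(0, -sqrt(3) / 2, 0))
  parc_tri <- parcellation(c("a", "b", "c", "d"), c("L", "R", "R", "L"), tri,
                           sphere_xyz = tri / sqrt(rowSums(tri^2)))
  vals <- mean_euclidean_distance(parc_tri)$values
  expect_equal(vals[vals < 1.01], rep(1, 2), tolerance = 1e-10)
})

test_that("participation coefficient evaluates the module formula", {
  parc <- toy_parcellation(2, network_id = c(1, 1, 2, 3))
  own <- toy_network(parc, list(c(1, 2, 1), c(3, 4, 1)))
  pc_own <- participation_coefficient(own, parc,
                                      assignments = c(1, 1, 2, 2))$values
  expect_equal(pc_own[1], 0)  # all weight inside its own module
  two <- toy_network(parc, list(c(1, 2, 1), c(1, 3, 1)))
  pc_two <- participation_coefficient(two, parc,
                                      assignments = c(1, 2, 3, 3))$values
  expect_equal(pc_two[1], 0.5)
  three <- toy_network(parc, list(c(1, 2, 1), c(1, 3, 1), c(1, 4, 1)))
  pc_three <- participation_coefficient(three, parc,
                                        assignments = c(1, 2, 3, 4))$values
  expect_equal(pc_three[1], 2 / 3)
  expect_error(participation_coefficient(two, parc, assignments = NULL),
               "assignment")
})

test_that("weighted clustering uses the max-normalised geometric mean", {
  parc <- toy_parcellation(2)
  tri_eq <- toy_network(parc, list(c(1, 2, 0.7), c(1, 3, 0.7), c(2, 3, 0.7),
                                   c(3, 4, 0.7)))
  cl <- clustering(tri_eq, parc)$values
  expect_equal(cl[1:2], c(1, 1))  # triangle of equal (max) weights
  path <- toy_network(parc, list(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1)))
  expect_equal(clustering(path, parc)$values, rep(0, 4))
  tri_w <- toy_network(parc, list(c(1, 2, 1), c(1, 3, 1), c(2, 3, 0.125),
                                  c(4, 1, 1)))
  clw <- clustering(tri_w, parc)$values
  expect_equal(clw[1], (1 * 1 * 0.125)^(1 / 3) * 2 / (3 * 2))
  expect_equal(clw[2], 0.5)  # node opposite the weak edge, degree 2
})

test_that("mean first passage time matches closed forms and simulation", {
  parc <- toy_parcellation(2)
  # two connected nodes embedded in a 4-region graph: direct dyad check
  dyad_parc <- parcellation(c("a", "b"), c("L", "R"),
                            rbind(c(-1, 0, 0), c(1, 0, 0)))
  dyad <- network(matrix(c(0, 1, 1, 0), 2), dyad_parc)
  m <- mean_first_passage_time(dyad, dyad_parc)
  expect_equal(m$values, c(1, 1), tolerance = 1e-10)

  # unweighted K_n: MFPT between distinct nodes is n - 1
  for (npc in c(2, 3)) {
    p <- toy_parcellation(npc)
    n <- p$n_regions
    kn <- network(matrix(1, n, n) - diag(n), p)
    mk <- mean_first_passage_time(kn, p)
    mat <- attr(mk, "mfpt_matrix")
    expect_equal(mat[upper.tri(mat)], rep(n - 1, sum(upper.tri(mat))),
                 tolerance = 1e-10)
    expect_equal(mk$values, rep(n - 1, n), tolerance = 1e-10)
  }

  # Kemeny constant: stationary-weighted MFPT identical from every start
  net <- random_connected_network(toy_parcellation(5), density = 0.4, seed = 2)
  mm <- attr(mean_first_passage_time(net, toy_parcellation(5)), "mfpt_matrix")
  pi_st <- rowSums(net$weights) / sum(net$weights)
  kemeny <- mm %*% pi_st
  expect_lt(max(kemeny) - min(kemeny), 1e-8)

  # simulation oracle on a small weighted graph
  sim_parc <- toy_parcellation(2)
  net4 <- random_connected_network(sim_parc, density = 0.7, seed = 3)
  mfpt <- attr(mean_first_passage_time(net4, sim_parc), "mfpt_matrix")
  p_mat <- net4$weights / rowSums(net4$weights)
  set.seed(9)
  n_walks <- 20000
  for (pair in list(c(1, 2), c(3, 1))) {
    cur <- rep(pair[1], n_walks)
    steps <- numeric(n_walks)
    alive <- rep(TRUE, n_walks)
    k <- 0
    while (any(alive) && k < 10000) {
      k <- k + 1
      idx <- which(alive)
      nxt <- vapply(cur[idx], function(v)
        sample.int(nrow(p_mat), 1, prob = p_mat[v, ]), integer(1))
      cur[idx] <- nxt
      arrived <- nxt == pair[2]
      steps[idx[arrived]] <- k
      alive[idx[arrived]] <- FALSE
    }
    est <- mean(steps)
    se <- stats::sd(steps) / sqrt(n_walks)
    expect_lt(abs(est - mfpt[pair[1], pair[2]]), 3 * se + 1e-6)
  }
})

test_that("the connectomic predictor table composes the seven metrics", {
  st <- shared_study()
  tab <- connectivity_predictors(st$weighted, st$parc)
  expect_equal(colnames(tab$matrix),
               c("strength", "betweenness", "closeness",
                 "euclidean_distance", "participation", "clustering", "mfpt"))
  expect_true(all(abs(colMeans(tab$matrix)) < 1e-10))
  expect_true(all(abs(apply(tab$matrix, 2, sd) - 1) < 1e-10))
  # columns reproduce the individual operations exactly (up to z-scoring)
  z <- function(v) (v - mean(v)) / sd(v)
  expect_equal(tab$matrix[, "strength"],
               z(strength(st$weighted, st$parc)$values),
               ignore_attr = TRUE)
  expect_equal(tab$matrix[, "mfpt"],
               z(mean_first_passage_time(st$weighted, st$parc)$values),
               ignore_attr = TRUE)
  # binary variant differs only in weight-dependent columns
  tab_b <- connectivity_predictors(binarize(st$weighted), st$parc)
  expect_equal(tab_b$matrix[, "euclidean_distance"],
               tab$matrix[, "euclidean_distance"], ignore_attr = TRUE)
})

test_that("permuting region order permutes every metric identically", {
  parc <- toy_parcellation(4)
  net <- random_connected_network(parc, density = 0.5, seed = 6)
  perm <- sample(8)
  # relabel so that the permuted parcellation reorders canonically to perm
  net_p <- network(net$weights[perm, perm], parc)
  for (metric in list(strength, betweenness, closeness, clustering,
                      mean_first_passage_time)) {
    ref <- metric(net, parc)$values
    expect_equal(metric(net_p, parc)$values, ref[perm], tolerance = 1e-9)
  }
})
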