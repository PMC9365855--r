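test_that("disorder similarity correlates regional profiles", {
  parc <- toy_parcellation(2)
  set.seed(60)
  # craft maps whose z-scored columns leave regions 1 and 2 with identical
  # profiles and region 3 with the exactly negated profile: each map is a
  # multiple of (1, 1, -1, -1), which is already centred
  a <- stats::rnorm(13)
  profiles <- cbind(a, a, -a, -a)  # rows = disorders; transpose below
  maps13 <- lapply(1:13, function(k)
    region_map(c(a[k], a[k], -a[k], -a[k]), parc, name = paste0("d", k)))
  sim <- disorder_similarity(maps13)
  expect_equal(sim$matrix[1, 2], 1, tolerance = 1e-12)
  expect_equal(sim$matrix[1, 3], -1, tolerance = 1e-12)
  expect_equal(diag(sim$matrix), rep(1, 4))
  expect_equal(sim$matrix, t(sim$matrix))
  expect_error(disorder_similarity(maps13[1:2]), "at least 3")

  # affine copies of one map leave every z-scored profile constant: all
  # pairs masked with a warning (correlation undefined)
  base_map <- stats::rnorm(4)
  affine <- lapply(1:13, function(k)
    region_map(k * base_map + 10 * k, parc))
  expect_warning(sim_flat <- disorder_similarity(affine), "masked")
  expect_true(all(is.na(sim_flat$matrix[upper.tri(sim_flat$matrix)])))
})

test_that("pair counts match the combinatorics of the parcellation", {
  spec <- synth_spec(seed = 61)
  parc <- make_parcellation(spec)
  maps <- lapply(1:13, function(k)
    region_map(stats::rnorm(68), parc, name = paste0("d", k)))
  sim <- disorder_similarity(maps)
  expect_length(upper_values(sim), 68 * 67 / 2)
  expect_equal(68 * 67 / 2, 2278)

  tab <- make_smooth_maps(parc, 7, seed = 61)
  left <- feature_similarity(tab, parc, hemisphere = "L")
  expect_equal(left$n_regions, 34)
  expect_length(upper_values(left), 34 * 33 / 2)
  expect_equal(34 * 33 / 2, 561)
})

test_that("leave-one-out influence flags outlier disorders", {
  spec <- synth_spec(seed = 62)
  parc <- make_parcellation(spec)
  base_tab <- make_smooth_maps(parc, 2, seed = 62)
  shared <- base_tab$matrix[, 1]

  # duplicated disorder maps have near-zero influence
  set.seed(1)
  concordant <- lapply(1:12, function(k)
    region_map(shared + 0.4 * stats::rnorm(68), parc, name = paste0("c", k)))
  dup <- c(concordant, list(region_map(concordant[[1]]$values, parc,
                                       name = "dup")))
  inf_dup <- influence(dup)
  expect_lt(inf_dup[13], stats::median(inf_dup))
  expect_lt(inf_dup[1], stats::median(inf_dup))
  expect_lt(max(inf_dup[c(1, 13)]), 0.05)
  # mutually positively correlated maps: influences nonnegative (numerically)
  expect_true(all(inf_dup >= -1e-12))

  # planted outlier carries the largest influence in most seeded runs
  hits <- 0
  for (s in 1:40) {
    set.seed(100 + s)
    maps <- lapply(1:12, function(k)
      region_map(shared + 0.3 * stats::rnorm(68), parc, name = paste0("c", k)))
    outlier <- region_map(stats::rnorm(68), parc, name = "outlier")
    inf <- influence(c(maps, list(outlier)))
    if (which.max(inf) == 13) hits <- hits + 1
  }
  expect_gte(hits, 38)
})

test_that("matrix correlation under spins preserves known structure", {
  spec <- synth_spec(seed = 63)
  parc <- make_parcellation(spec)
  spins <- generate_spins(parc, n = 100, seed = 63)
  tab <- make_smooth_maps(parc, 7, seed = 63)
  sim <- feature_similarity(tab)
  self <- matrix_correlation(sim, sim, spins)
  expect_equal(self$r, 1, tolerance = 1e-12)
  expect_equal(self$n_pairs, 2278)

  # conjugating by a bijective permutation contained in the nulls puts
  # r = 1 in the null distribution (nearest-neighbour spins need not be
  # bijections, so build a known-permutation ensemble by hand)
  set.seed(1)
  p1 <- sample.int(68)
  perm_ens <- structure(list(method = "spin",
                             permutations = rbind(p1, spins$permutations),
                             n = spins$n + 1L, seed = 1L, n_regions = 68L),
                        class = "null_ensemble")
  inv <- integer(68); inv[p1] <- seq_len(68)
  b <- sim
  b$matrix <- sim$matrix[inv, inv]
  mc <- matrix_correlation(sim, b, perm_ens)
  expect_true(any(abs(mc$null_r - 1) < 1e-12))
})

test_that("similarity outputs are location-invariant per disorder", {
  spec <- synth_spec(seed = 64)
  parc <- make_parcellation(spec)
  set.seed(64)
  maps <- lapply(1:6, function(k) region_map(stats::rnorm(68), parc))
  shifted <- maps
  shifted[[3]] <- region_map(maps[[3]]$values + 100, parc)
  expect_equal(disorder_similarity(maps)$matrix,
               disorder_similarity(shifted)$matrix, tolerance = 1e-10)
})

test_that("connected/unconnected contrast detects planted edge effects", {
  st <- shared_study()
  ut <- upper.tri(st$consensus$weights)
  nulls <- suppressWarnings(rewire_preserving(st$consensus, st$parc,
                                              n_ensembles = 100, seed = 65))

  # partition identity
  set.seed(65)
  m <- matrix(stats::rnorm(68^2), 68, 68); m <- (m + t(m)) / 2; diag(m) <- 1
  sim <- structure(list(matrix = m, source = "disorder",
                        masked = rep(FALSE, 68), n_regions = 68),
                   class = "similarity_matrix")
  res <- connected_vs_unconnected(sim, st$consensus, nulls)
  expect_equal(res$n_connected + res$n_unconnected, 68 * 67 / 2)

  # constant similarity: zero difference
  sim0 <- sim; sim0$matrix[,] <- 0.3; diag(sim0$matrix) <- 1
  expect_equal(connected_vs_unconnected(sim0, st$consensus, nulls)$diff, 0)

  # planted +0.2 on SC edges: detected against the rewired null
  detected <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    noise <- matrix(stats::rnorm(68^2, sd = 0.1), 68, 68)
    planted <- 0.2 * (st$consensus$weights > 0) + (noise + t(noise)) / 2
    diag(planted) <- 1
    simp <- sim; simp$matrix <- planted
    r <- connected_vs_unconnected(simp, st$consensus, nulls)
    if (r$diff > 0 && r$p < 0.05) detected <- detected + 1
  }
  expect_gte(detected, 19)
})

test_that("within/between-network contrast responds to planted blocks", {
  spec <- synth_spec(seed = 66)
  parc <- make_parcellation(spec)
  spins <- generate_spins(parc, n = 200, seed = 66)
  a <- parc$network_id

  # block-structured similarity aligned with the assignments
  set.seed(66)
  noise <- matrix(stats::rnorm(68^2, sd = 0.05), 68, 68)
  block <- 0.3 * outer(a, a, "==") + (noise + t(noise)) / 2
  diag(block) <- 1
  sim <- structure(list(matrix = block, source = "disorder",
                        masked = rep(FALSE, 68), n_regions = 68),
                   class = "similarity_matrix")
  res <- within_between_networks(sim, a, spins)
  expect_gt(res$diff, 0)
  expect_lt(res$p_spin, 0.05)
  same <- outer(a, a, "==")[upper.tri(block)]
  expect_equal(res$n_within + res$n_between, 68 * 67 / 2)
  expect_equal(res$n_within, sum(same))

  expect_error(within_between_networks(sim, seq_len(68), spins), "distinct")
  expect_error(within_between_networks(sim, rep(1, 68), spins), "two networks")
})

test_that("distance regression removes and only removes distance structure", {
  spec <- synth_spec(seed = 67)
  parc <- make_parcellation(spec)
  d <- centroid_distances(parc)
  ut <- upper.tri(d)

  # entries exactly linear in distance: residuals vanish
  lin <- 2 - 0.5 * d; diag(lin) <- 0
  r0 <- distance_regress(lin, parc)
  expect_lt(max(abs(r0[ut])), 1e-10)

  # residuals orthogonal to distance; idempotent
  set.seed(67)
  noise <- matrix(stats::rnorm(68^2), 68, 68)
  m <- 1 - 0.3 * d + (noise + t(noise)) / 2; diag(m) <- 0
  r1 <- distance_regress(m, parc)
  expect_lt(abs(stats::cor(r1[ut], d[ut])), 1e-10)
  r2 <- distance_regress(r1, parc)
  expect_equal(r2, r1, tolerance = 1e-10)
  expect_equal(diag(r1), rep(0, 68))

  # exponential variant also leaves distance-uncorrelated residuals
  r3 <- distance_regress(m, parc, model = "exponential")
  expect_lt(abs(stats::cor(r3[ut], d[ut])), 0.05)
})
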