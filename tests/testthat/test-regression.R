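test_that("fit_multilinear reproduces OLS identities", {
  parc <- toy_parcellation(34)
  x <- make_smooth_maps(parc, 7, seed = 1)
  # noiseless: perfect fit
  y0 <- make_abnormality_linear(x, parc, c(0.5, -1, 0, 2, 0, 0, 0.3),
                                noise_sd = 0, seed = 1)
  f0 <- fit_multilinear(x, y0)
  expect_equal(f0$r2, 1, tolerance = 1e-12)
  expect_equal(f0$r2_adj, 1, tolerance = 1e-12)
  expect_lt(max(abs(f0$residuals)), 1e-10)

  # adjusted R2 formula at r2 = 0.5, n = 68, p = 7
  expect_equal(1 - 0.5 * 67 / 60, 0.4416667, tolerance = 1e-6)
  y <- make_abnormality_linear(x, parc, c(1, rep(0, 6)),
                               noise_sd = noise_for_r2(x, c(1, rep(0, 6)), 0.5),
                               seed = 3)
  f <- fit_multilinear(x, y)
  expect_equal(f$r2_adj, 1 - (1 - f$r2) * 67 / 60, tolerance = 1e-12)

  # agreement with lm() as an independent route
  lmfit <- summary(stats::lm(scale(y$values) ~ x$matrix))
  expect_equal(f$r2, lmfit$r.squared, tolerance = 1e-10)
  expect_equal(f$r2_adj, lmfit$adj.r.squared, tolerance = 1e-10)

  # unstandardized predictors refused; collinear design named
  raw <- predictor_table(x$matrix, parc, family = "molecular")
  expect_error(fit_multilinear(raw, y), "z-scored")
  dup <- zscore_columns(predictor_table(cbind(x$matrix[, 1:3],
                                              again = x$matrix[, 1]), parc,
                                        family = "molecular"))
  expect_error(fit_multilinear(dup, y), "collinear")
})

test_that("null designs give near-zero adjusted R2 on average", {
  parc <- toy_parcellation(34)
  x <- make_smooth_maps(parc, 7, seed = 2)
  stats_null <- vapply(1:200, function(s) {
    set.seed(10000 + s)
    y <- region_map(stats::rnorm(68), parc)
    f <- fit_multilinear(x, y)
    c(f$r2, f$r2_adj)
  }, numeric(2))
  expect_lt(abs(mean(stats_null[1, ]) - 7 / 67), 0.03)  # E[R2] = p/(n-1)
  expect_lt(abs(mean(stats_null[2, ])), 0.03)
})

test_that("dominance analysis conserves R2 and matches the brute-force oracle", {
  parc <- toy_parcellation(34)
  # p = 1: dominance equals the simple-regression r2
  x1 <- make_smooth_maps(parc, 1, seed = 4)
  set.seed(5)
  y <- region_map(x1$matrix[, 1] * 2 + stats::rnorm(68), parc)
  d1 <- dominance_analysis(x1, y)
  expect_equal(unname(d1$total_dominance), d1$r2, tolerance = 1e-12)

  # two orthogonal predictors: marginal r2s are the dominances
  v1 <- rep(c(1, -1), 34); v2 <- rep(c(1, 1, -1, -1), 17)
  x2 <- zscore_columns(predictor_table(cbind(a = v1, b = v2), parc,
                                       family = "molecular"))
  y2 <- region_map(0.75 * drop(scale(v1)) + stats::rnorm(68, sd = 1e-8), parc)
  d2 <- dominance_analysis(x2, y2)
  ycent <- drop(scale(y2$values))
  marg_a <- summary(stats::lm(ycent ~ v1))$r.squared
  expect_equal(unname(d2$total_dominance["a"]), marg_a, tolerance = 1e-6)
  expect_lt(d2$total_dominance["b"], 1e-6)

  # conservation and oracle equality on random p = 5 problems
  parc5 <- toy_parcellation(20)
  for (s in 1:25) {
    set.seed(s)
    xm <- matrix(stats::rnorm(40 * 5), 40, 5)
    x <- zscore_columns(predictor_table(xm, parc5,
                                        column_names = paste0("p", 1:5),
                                        family = "molecular"))
    ym <- region_map(drop(xm %*% stats::rnorm(5)) + stats::rnorm(40), parc5)
    d <- dominance_analysis(x, ym)
    expect_lt(abs(sum(d$total_dominance) - d$r2), 1e-9)
    expect_equal(sum(d$scaled_dominance), d$r2_adj, tolerance = 1e-9)
    oracle <- brute_force_dominance(x$matrix, drop(scale(ym$values)))
    expect_equal(unname(d$total_dominance), oracle, tolerance = 1e-10)
  }

  # enumeration guard
  big <- zscore_columns(predictor_table(matrix(stats::rnorm(68 * 21), 68, 21),
                                        parc,
                                        column_names = paste0("c", 1:21),
                                        family = "molecular"))
  expect_error(dominance_analysis(big, y), "guard|subset")
})

test_that("irrelevant orthogonalised predictors receive near-zero dominance", {
  parc <- toy_parcellation(34)
  doms <- vapply(1:100, function(s) {
    set.seed(s)
    xm <- matrix(stats::rnorm(68 * 4), 68, 4)
    # last predictor orthogonal to the others and to the signal
    xm[, 4] <- stats::residuals(stats::lm(xm[, 4] ~ xm[, 1:3]))
    x <- zscore_columns(predictor_table(xm, parc,
                                        column_names = paste0("p", 1:4),
                                        family = "molecular"))
    y <- region_map(drop(xm[, 1:3] %*% c(1, 0.5, -0.5)) + stats::rnorm(68),
                    parc)
    dominance_analysis(x, y)$total_dominance[4]
  }, numeric(1))
  expect_lt(mean(doms), 0.01)
})

test_that("distance-dependent CV splits by proximity and predicts held-out maps", {
  spec <- synth_spec(seed = 21)
  parc <- make_parcellation(spec)
  x <- make_smooth_maps(parc, 7, seed = 21)
  b <- c(1, -0.5, 0.5, 0, 0, 0, 0)
  y <- make_abnormality_linear(x, parc, b,
                               noise_sd = noise_for_r2(x, b, 0.6), seed = 2)
  cv <- distance_cv(x, y, parc, n_iter = 100, seed = 3)
  expect_equal(cv$n_train, 51)
  expect_equal(cv$n_test, 17)
  expect_length(cv$test_correlation, 100)

  # exact linear map: every test correlation 1
  y0 <- make_abnormality_linear(x, parc, b, noise_sd = 0, seed = 2)
  cv0 <- distance_cv(x, y0, parc, n_iter = 20, seed = 4)
  expect_true(all(abs(cv0$test_correlation - 1) < 1e-8))

  # planted R2 = 0.6: positive out-of-sample, below in-sample correlation
  med <- vapply(1:50, function(s) {
    ys <- make_abnormality_linear(x, parc, b,
                                  noise_sd = noise_for_r2(x, b, 0.6),
                                  seed = 100 + s)
    cvs <- distance_cv(x, ys, parc, n_iter = 50, seed = s)
    fit <- fit_multilinear(x, ys)
    c(stats::median(cvs$test_correlation, na.rm = TRUE), sqrt(fit$r2))
  }, numeric(2))
  expect_gt(stats::median(med[1, ]), 0)
  expect_lt(mean(med[1, ]), mean(med[2, ]))

  # reproducibility
  expect_identical(distance_cv(x, y, parc, n_iter = 10, seed = 9),
                   distance_cv(x, y, parc, n_iter = 10, seed = 9))
})

test_that("fit_family_models produces one fit per map and family", {
  spec <- synth_spec(seed = 33)
  parc <- make_parcellation(spec)
  mol <- make_smooth_maps(parc, 7, seed = 33)
  con <- make_smooth_maps(parc, 7, seed = 34, family = "connectomic")
  maps <- lapply(1:5, function(i)
    make_abnormality_linear(mol, parc, stats::rnorm(7), 0.5, seed = i))
  names(maps) <- paste0("disorder_", 1:5)
  res <- fit_family_models(maps, list(molecular = mol, connectomic = con))
  expect_equal(nrow(res), 10)
  expect_equal(sort(unique(res$family)), c("connectomic", "molecular"))
  expect_true(all(res$r2 >= 0 & res$r2 <= 1))
})

test_that("variance-ratio comparison behaves at its edge cases", {
  parc <- toy_parcellation(34)
  x <- make_smooth_maps(parc, 3, seed = 41)
  set.seed(42)
  y1 <- region_map(x$matrix[, 1] + stats::rnorm(68, sd = 0.5), parc)
  f1 <- fit_multilinear(x, y1)
  expect_equal(compare_fits_f(f1, f1)$f, 1)

  # doubling residual variance doubles the ratio: construct directly
  f2 <- f1
  f2$residuals <- f1$residuals * sqrt(2)
  expect_equal(compare_fits_f(f1, f2)$f, 2, tolerance = 1e-12)

  y0 <- region_map(x$matrix[, 1], parc)
  f0 <- fit_multilinear(x, y0)
  expect_error(compare_fits_f(f0, f0), "zero residual")
})
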