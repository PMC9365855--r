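# Multilinear abnormality models: OLS fit, dominance analysis (full
# submodel enumeration), distance-dependent cross-validation, and a
# variance-ratio utility for comparing fits.

# internal: R^2 of y on the columns `cols` of x (with intercept), via QR
r2_subset <- function(x, y, cols) {
  if (length(cols) == 0) return(0)
  fit <- stats::lm.fit(cbind(1, x[, cols, drop = FALSE]), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

#' Fit a multilinear abnormality model
#'
#' Ordinary least squares of an abnormality map on a standardized
#' predictor table, with intercept. The response is z-scored before
#' fitting so model fits are comparable across maps. Reports both R^2 and
#' the adjusted value R^2_adj = 1 - (1 - R^2)(n - 1)/(n - p - 1).
#'
#' @param predictors a standardized `predictor_table`.
#' @param map a `region_map` response.
#' @return A `model_fit` list: coefficients, intercept, r2, r2_adj,
#'   fitted, residuals, n, p.
#' @export
fit_multilinear <- function(predictors, map) {
  stopifnot(inherits(predictors, "predictor_table"),
            inherits(map, "region_map"))
  if (!predictors$standardized)
    stop("predictors must be z-scored before fitting")
  x <- predictors$matrix
  if (nrow(x) != map$n_regions) stop("predictors and map are misaligned")
  n <- nrow(x); p <- ncol(x)
  if (n <= p + 1) stop("need n > p + 1 observations")
  qrx <- qr(cbind(1, x))
  if (qrx$rank < p + 1) {
    drop_cols <- setdiff(seq_len(p), qrx$pivot[seq_len(qrx$rank)] - 1)
    stop("rank-deficient design; collinear column(s): ",
         paste(predictors$column_names[drop_cols], collapse = ", "))
  }
  y <- zscore(map$values)
  coefs <- qr.coef(qrx, y)
  fitted <- drop(cbind(1, x) %*% coefs)
  resid <- y - fitted
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  structure(list(coefficients = stats::setNames(coefs[-1],
                                                predictors$column_names),
                 intercept = coefs[1], r2 = r2, r2_adj = r2_adj,
                 fitted = fitted, residuals = resid, n = n, p = p),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit: n = %d, p = %d, R2 = %.4f, adj R2 = %.4f\n",
              x$n, x$p, x$r2, x$r2_adj))
  invisible(x)
}

#' Dominance analysis of a multilinear model
#'
#' Decomposes the fit of the full model into per-predictor contributions
#' by enumerating all 2^p - 1 submodels. The total dominance of a
#' predictor is the average, over submodel sizes, of the mean increase in
#' R^2 when that predictor is added to a submodel of the remaining
#' predictors. Total dominances sum exactly to the full-model R^2; a
#' proportionally rescaled variant sums to the adjusted R^2 (the scale on
#' which contributions are usually reported). No per-predictor
#' significance tests are computed: dominances are relative to the other
#' predictors in the model.
#'
#' @param predictors a standardized `predictor_table` with p <= `max_p`.
#' @param map a `region_map` response.
#' @param max_p enumeration guard (default 20).
#' @return A `dominance_result`: total_dominance, scaled_dominance
#'   (summing to adjusted R^2), percent contributions, full-model r2 and
#'   r2_adj.
#' @export
dominance_analysis <- function(predictors, map, max_p = 20L) {
  stopifnot(inherits(predictors, "predictor_table"),
            inherits(map, "region_map"))
  x <- predictors$matrix
  p <- ncol(x)
  if (p > max_p)
    stop(sprintf("p = %d exceeds the enumeration guard (%d); fit a predictor subset",
                 p, max_p))
  full <- fit_multilinear(predictors, map)  # validates rank, n > p + 1
  y <- zscore(map$values)

  # R^2 for every subset, indexed by bitmask
  n_sub <- 2^p
  r2 <- numeric(n_sub)       # r2[mask + 1]
  for (mask in seq_len(n_sub - 1)) {
    cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) > 0)
    r2[mask + 1] <- r2_subset(x, y, cols)
  }

  total <- numeric(p)
  for (i in seq_len(p)) {
    bit_i <- bitwShiftL(1L, i - 1L)
    others <- setdiff(seq_len(p), i)
    # increments grouped by subset size k = 0 .. p-1; note combn() must
    # never see a scalar first argument (it would expand it to a range)
    inc_by_size <- vapply(0:(p - 1), function(k) {
      subs <- if (k == 0) list(integer(0))
              else if (length(others) == 1) list(others)
              else utils::combn(others, k, simplify = FALSE)
      mean(vapply(subs, function(s) {
        mask <- sum(bitwShiftL(1L, s - 1L))
        r2[mask + bit_i + 1] - r2[mask + 1]
      }, numeric(1)))
    }, numeric(1))
    total[i] <- mean(inc_by_size)
  }
  names(total) <- predictors$column_names
  scaled <- if (full$r2 > 0) total * full$r2_adj / full$r2 else total
  structure(list(total_dominance = total,
                 scaled_dominance = scaled,
                 percent = if (full$r2 > 0) 100 * total / full$r2
                           else rep(NA_real_, p),
                 r2 = full$r2, r2_adj = full$r2_adj),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat(sprintf("dominance_result: full R2 = %.4f (adj %.4f)\n", x$r2, x$r2_adj))
  print(round(x$total_dominance, 4))
  invisible(x)
}

#' Distance-dependent cross-validation
#'
#' Per iteration, a source region is chosen uniformly at random; the
#' training set is the floor(train_frac * N) regions closest to it in
#' centroid Euclidean distance (the source included; distance ties broken
#' by region order), and the test set is the remainder. The model is fit
#' on the training regions and the Pearson correlation between predicted
#' and observed abnormality on the test regions is recorded. Splitting by
#' spatial proximity rather than at random keeps spatially autocorrelated
#' maps from leaking between train and test.
#'
#' @param predictors a standardized `predictor_table`.
#' @param map a `region_map` response.
#' @param parc the aligned `parcellation`.
#' @param n_iter number of iterations.
#' @param train_frac training fraction (default 0.75).
#' @param seed integer seed.
#' @return A `cv_result`: test_correlation per iteration (NA where the
#'   test response was degenerate), source region indices, train size.
#' @export
distance_cv <- function(predictors, map, parc, n_iter = 1000,
                        train_frac = 0.75, seed = 1L) {
  stopifnot(inherits(predictors, "predictor_table"),
            inherits(map, "region_map"))
  x <- predictors$matrix
  n <- nrow(x)
  check_aligned(n, parc, "predictor table")
  n_train <- floor(train_frac * n)
  if (n_train <= ncol(x) + 1) stop("training set too small for the model")
  d <- centroid_distances(parc)
  y <- zscore(map$values)
  set.seed(seed)
  sources <- sample.int(n, n_iter, replace = TRUE)
  test_cor <- vapply(sources, function(src) {
    ord <- order(d[src, ])          # ties broken by region order
    train <- ord[seq_len(n_train)]
    test <- setdiff(seq_len(n), train)
    fit <- stats::lm.fit(cbind(1, x[train, , drop = FALSE]), y[train])
    pred <- drop(cbind(1, x[test, , drop = FALSE]) %*% fit$coefficients)
    if (stats::sd(y[test]) < 1e-12 || stats::sd(pred) < 1e-12) {
      warning("degenerate test-set variance; iteration recorded as NA")
      return(NA_real_)
    }
    stats::cor(pred, y[test])
  }, numeric(1))
  structure(list(test_correlation = test_cor, sources = sources,
                 n_train = n_train, n_test = n - n_train,
                 n_iter = n_iter, seed = seed),
            class = "cv_result")
}

#' Fit every abnormality map against every predictor family
#'
#' Convenience wrapper for the cross-disorder design: one multilinear fit
#' per (map, predictor-family) pair, returned as a tidy table of fit
#' statistics with the fits attached.
#'
#' @param maps named list of `region_map` abnormality maps.
#' @param tables named list of standardized `predictor_table` objects
#'   (one per family).
#' @return Data frame with one row per map x family (columns map, family,
#'   r2, r2_adj, n, p) and the `model_fit` objects in attribute `fits`.
#' @export
fit_family_models <- function(maps, tables) {
  stopifnot(length(maps) >= 1, length(tables) >= 1)
  if (is.null(names(maps))) names(maps) <- sprintf("map_%02d", seq_along(maps))
  if (is.null(names(tables)))
    names(tables) <- vapply(tables, function(t) t$family, character(1))
  grid <- expand.grid(map = names(maps), family = names(tables),
                      stringsAsFactors = FALSE)
  fits <- Map(function(m, f) fit_multilinear(tables[[f]], maps[[m]]),
              grid$map, grid$family)
  grid$r2 <- vapply(fits, function(f) f$r2, numeric(1))
  grid$r2_adj <- vapply(fits, function(f) f$r2_adj, numeric(1))
  grid$n <- vapply(fits, function(f) f$n, numeric(1))
  grid$p <- vapply(fits, function(f) f$p, numeric(1))
  attr(grid, "fits") <- fits
  grid
}

#' Variance-ratio comparison of two model fits
#'
#' Ratio of residual mean squares (larger over smaller) between two fits
#' with the same number of predictors on independent samples, with its
#' degrees-of-freedom pair. A generic F-type utility for asking whether
#' one fit is materially noisier than another; no claim of an exact
#' sampling distribution is attached.
#'
#' @param fit_a,fit_b `model_fit` objects with equal p.
#' @return List with `f` (>= 1), `df` (numerator, denominator), and
#'   `order` ("a/b" or "b/a").
#' @export
compare_fits_f <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "model_fit"), inherits(fit_b, "model_fit"))
  if (fit_a$p != fit_b$p) stop("fits must have the same number of predictors")
  ms <- function(f) sum(f$residuals^2) / (f$n - f$p - 1)
  a <- ms(fit_a); b <- ms(fit_b)
  # fits are on z-scored responses, so a mean square at rounding level
  # means a noiseless fit
  if (a < 1e-12 || b < 1e-12)
    stop("zero residual variance; ratio undefined")
  if (a >= b) list(f = a / b, df = c(fit_a$n - fit_a$p - 1,
                                     fit_b$n - fit_b$p - 1), order = "a/b")
  else list(f = b / a, df = c(fit_b$n - fit_b$p - 1,
                              fit_a$n - fit_a$p - 1), order = "b/a")
}
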