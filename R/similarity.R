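# Inter-regional similarity: disorder similarity, leave-one-out influence,
# feature similarity, matrix-level comparisons against spin and rewired
# nulls, the connected/unconnected and within/between-network contrasts,
# and distance regression.

# internal: correlation between rows of a region x feature matrix, with
# masking of constant rows
row_similarity <- function(m, source) {
  sds <- apply(m, 1, stats::sd)
  const <- sds < 1e-12
  sim <- matrix(NA_real_, nrow(m), nrow(m))
  ok <- which(!const)
  if (length(ok) >= 2)
    sim[ok, ok] <- stats::cor(t(m[ok, , drop = FALSE]))
  diag(sim) <- 1
  if (any(const))
    warning(sprintf("%d region(s) with constant profiles masked in %s similarity",
                    sum(const), source))
  structure(list(matrix = sim, source = source, masked = const,
                 n_regions = nrow(m)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix (%s): %d regions%s\n", x$source,
              x$n_regions,
              if (any(x$masked)) sprintf(" (%d masked)", sum(x$masked))
              else ""))
  invisible(x)
}

#' Upper-triangle values of a similarity matrix or network
#'
#' @param x a `similarity_matrix`, `network`, or plain square matrix.
#' @return Numeric vector of the strictly-upper-triangular entries.
#' @export
upper_values <- function(x) {
  m <- if (inherits(x, "similarity_matrix")) x$matrix
       else if (inherits(x, "network")) x$weights
       else as.matrix(x)
  m[upper.tri(m)]
}

#' Disorder similarity matrix
#'
#' For every region, its across-disorder abnormality profile is the vector
#' of its values over the supplied maps; the disorder similarity of two
#' regions is the Pearson correlation of their profiles. Each map is
#' z-scored first (abnormality maps are effect sizes on a common z scale;
#' this also makes the similarity invariant to shifting or positively
#' rescaling any single map). Regions similarly affected across disorders
#' get high similarity.
#'
#' @param maps list of >= 3 `region_map` objects on a common parcellation.
#' @return A `similarity_matrix` with source "disorder".
#' @export
disorder_similarity <- function(maps) {
  if (length(maps) < 3) stop("need at least 3 maps to correlate profiles")
  for (m in maps) stopifnot(inherits(m, "region_map"))
  if (length(unique(vapply(maps, function(m) m$n_regions, 1L))) != 1)
    stop("maps are misaligned")
  profile <- vapply(maps, function(m) zscore(m$values),
                    numeric(maps[[1]]$n_regions))
  row_similarity(profile, "disorder")
}

#' Leave-one-out influence of each disorder on the similarity matrix
#'
#' For each disorder i, the disorder similarity matrix is recomputed with
#' that disorder excluded and compared to the full matrix:
#' I_i = 1 - corr(D, D_i) over the upper triangles. Disorders whose
#' removal barely changes the similarity structure get influence near 0.
#'
#' @param maps list of >= 4 `region_map` objects.
#' @return Named numeric vector of influences, with the leave-one-out
#'   correlations attached as attribute `loo_correlation`.
#' @export
influence <- function(maps) {
  if (length(maps) < 4) stop("need at least 4 maps for leave-one-out")
  full <- disorder_similarity(maps)
  full_ut <- upper_values(full)
  loo_r <- vapply(seq_along(maps), function(i) {
    di <- disorder_similarity(maps[-i])
    stats::cor(full_ut, upper_values(di), use = "complete.obs")
  }, numeric(1))
  nm <- vapply(seq_along(maps), function(i) {
    n <- maps[[i]]$name
    if (is.null(n) || n == "map") paste0("map_", i) else n
  }, character(1))
  out <- stats::setNames(1 - loo_r, nm)
  attr(out, "loo_correlation") <- stats::setNames(loo_r, nm)
  out
}

#' Feature similarity matrix
#'
#' Region x region Pearson correlation of regional feature profiles
#' (molecular predictors, receptor densities, gene expression, ...).
#' Feature columns are z-scored (within the selected regions) before the
#' row correlation so features on different scales contribute equally. For
#' annotations only measured reliably in one hemisphere (the gene case)
#' the similarity can be restricted to that hemisphere.
#'
#' @param table a `predictor_table` or `annotation_matrix` with >= 3
#'   columns.
#' @param parc the aligned `parcellation` (needed for hemisphere
#'   restriction).
#' @param hemisphere optional "L" or "R" to restrict regions.
#' @return A `similarity_matrix`.
#' @export
feature_similarity <- function(table, parc = NULL, hemisphere = NULL) {
  m <- if (inherits(table, "predictor_table")) table$matrix
       else if (inherits(table, "annotation_matrix")) table$matrix
       else stop("table must be a predictor_table or annotation_matrix")
  if (ncol(m) < 3) stop("need at least 3 feature columns")
  src <- if (inherits(table, "predictor_table")) table$family else "annotation"
  if (!is.null(hemisphere)) {
    if (is.null(parc)) stop("hemisphere restriction needs the parcellation")
    stopifnot(hemisphere %in% c("L", "R"))
    m <- m[parc$hemisphere == hemisphere, , drop = FALSE]
    src <- paste0(src, "_", hemisphere)
  }
  csd <- apply(m, 2, stats::sd)
  if (any(csd < 1e-12))
    stop("constant feature column(s): ",
         paste(colnames(m)[csd < 1e-12], collapse = ", "))
  row_similarity(scale(m), src)
}

#' Correlate two similarity structures with spin significance
#'
#' Pearson correlation of the upper triangles (diagonal excluded) of two
#' region x region matrices, with a two-sided spin test: each spin
#' permutation is applied to the rows and columns of the second matrix
#' (conjugation, so its internal structure is preserved) and the
#' correlation recomputed.
#'
#' @param a,b `similarity_matrix`, `network`, or square matrix on the same
#'   parcellation.
#' @param spins spin `null_ensemble`.
#' @return List with `r`, `p_spin`, `null_r`, and `n_pairs` (the number of
#'   upper-triangle pairs used).
#' @export
matrix_correlation <- function(a, b, spins) {
  ma <- if (inherits(a, "similarity_matrix")) a$matrix
        else if (inherits(a, "network")) a$weights else as.matrix(a)
  mb <- if (inherits(b, "similarity_matrix")) b$matrix
        else if (inherits(b, "network")) b$weights else as.matrix(b)
  if (!all(dim(ma) == dim(mb))) stop("matrix size mismatch")
  stopifnot(inherits(spins, "null_ensemble"), spins$method == "spin",
            spins$n_regions == nrow(ma))
  ut <- upper.tri(ma)
  ok <- ut & !is.na(ma) & !is.na(mb)
  r_obs <- stats::cor(ma[ok], mb[ok])
  r_null <- vapply(seq_len(spins$n), function(k) {
    p <- spins$permutations[k, ]
    mbp <- mb[p, p]
    ok_k <- ut & !is.na(ma) & !is.na(mbp)
    stats::cor(ma[ok_k], mbp[ok_k])
  }, numeric(1))
  list(r = r_obs, p_spin = spin_pvalue(r_obs, r_null, sided = "two"),
       null_r = r_null, n_pairs = sum(ok))
}

#' Connected versus unconnected similarity contrast
#'
#' Difference between the mean similarity of structurally connected region
#' pairs and unconnected pairs, tested one-sided against a degree- and
#' edge-length-preserving rewired null: the same difference is recomputed
#' with each rewired network defining the connected set, and
#' p = (1 + #{null >= observed}) / (n + 1).
#'
#' @param sim a `similarity_matrix`.
#' @param sc_binary binary structural `network`.
#' @param nulls rewire `null_ensemble` generated from `sc_binary`.
#' @return List with `diff`, `p`, `null_diff`, `n_connected`,
#'   `n_unconnected`.
#' @export
connected_vs_unconnected <- function(sim, sc_binary, nulls) {
  stopifnot(inherits(sim, "similarity_matrix"),
            inherits(sc_binary, "network"),
            inherits(nulls, "null_ensemble"), nulls$method == "rewire")
  if (length(nulls$networks) == 0) stop("empty null ensemble")
  ut <- upper.tri(sim$matrix)
  s <- sim$matrix
  contrast <- function(adj) {
    conn <- ut & adj > 0
    unconn <- ut & adj == 0
    mean(s[conn], na.rm = TRUE) - mean(s[unconn], na.rm = TRUE)
  }
  obs <- contrast(sc_binary$weights)
  null_diff <- vapply(nulls$networks, function(nn) contrast(nn$weights),
                      numeric(1))
  list(diff = obs,
       p = (1 + sum(null_diff >= obs)) / (length(null_diff) + 1),
       null_diff = null_diff,
       n_connected = sum(ut & sc_binary$weights > 0),
       n_unconnected = sum(ut & sc_binary$weights == 0))
}

#' Within- versus between-network similarity contrast
#'
#' Difference between the mean similarity of region pairs in the same
#' intrinsic network and pairs in different networks, tested one-sided by
#' spinning the network-assignment vector (spatial-autocorrelation-
#' preserving) and recomputing the difference.
#'
#' @param sim a `similarity_matrix`.
#' @param assignments integer network label per region.
#' @param spins spin `null_ensemble`.
#' @return List with `diff`, `p_spin`, `null_diff`, `n_within`,
#'   `n_between`.
#' @export
within_between_networks <- function(sim, assignments, spins) {
  stopifnot(inherits(sim, "similarity_matrix"),
            inherits(spins, "null_ensemble"), spins$method == "spin")
  assignments <- as.integer(assignments)
  stopifnot(length(assignments) == sim$n_regions)
  if (length(unique(assignments)) < 2) stop("need at least two networks")
  if (length(unique(assignments)) == length(assignments))
    stop("all assignments distinct: no within-network pairs")
  ut <- upper.tri(sim$matrix)
  s <- sim$matrix
  contrast <- function(a) {
    same <- outer(a, a, "==")
    mean(s[ut & same], na.rm = TRUE) - mean(s[ut & !same], na.rm = TRUE)
  }
  obs <- contrast(assignments)
  null_diff <- vapply(seq_len(spins$n), function(k)
    contrast(assignments[spins$permutations[k, ]]), numeric(1))
  same <- outer(assignments, assignments, "==")
  list(diff = obs,
       p_spin = (1 + sum(null_diff >= obs, na.rm = TRUE)) /
         (sum(!is.na(null_diff)) + 1),
       null_diff = null_diff,
       n_within = sum(ut & same), n_between = sum(ut & !same))
}

#' Regress distance out of a similarity or connectivity matrix
#'
#' OLS of the upper-triangle entries on pairwise centroid Euclidean
#' distance (with intercept, linear by default or exponential-decay on
#' request); residuals are re-packed into a symmetric matrix with zero
#' diagonal. Used as an alternative to spin tests for removing the
#' distance dependence shared by most inter-regional matrices.
#'
#' @param mat a `similarity_matrix`, `network`, or square matrix.
#' @param parc the aligned `parcellation`.
#' @param model "linear" (entries ~ distance) or "exponential"
#'   (entries ~ exp(-distance / scale), scale fit by nonlinear least
#'   squares falling back to the linear model on failure).
#' @return Square symmetric residual matrix, zero diagonal.
#' @export
distance_regress <- function(mat, parc, model = c("linear", "exponential")) {
  model <- match.arg(model)
  m <- if (inherits(mat, "similarity_matrix")) mat$matrix
       else if (inherits(mat, "network")) mat$weights else as.matrix(mat)
  check_aligned(nrow(m), parc, "matrix")
  d <- centroid_distances(parc)
  ut <- upper.tri(m)
  yv <- m[ut]; dv <- d[ut]
  ok <- !is.na(yv)
  if (stats::sd(dv[ok]) < 1e-12) stop("constant pairwise distances")
  res <- rep(NA_real_, length(yv))
  if (model == "linear") {
    fit <- stats::lm.fit(cbind(1, dv[ok]), yv[ok])
    res[ok] <- fit$residuals
  } else {
    df <- data.frame(y = yv[ok], d = dv[ok])
    fit <- tryCatch(
      stats::nls(y ~ a * exp(-d / s) + c0, data = df,
                 start = list(a = stats::sd(df$y), s = mean(df$d),
                              c0 = mean(df$y))),
      error = function(e) NULL)
    if (is.null(fit)) {
      lf <- stats::lm.fit(cbind(1, dv[ok]), yv[ok])
      res[ok] <- lf$residuals
    } else res[ok] <- stats::residuals(fit)
  }
  out <- matrix(0, nrow(m), ncol(m))
  out[ut] <- res
  out <- out + t(out)
  diag(out) <- 0
  out
}
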