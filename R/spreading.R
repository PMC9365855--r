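# Network spreading: neighbour abnormality (SC- and SC+FC-weighted), the
# node-neighbour spreading correlation with spin-test significance,
# epicentre likelihood, and cross-disorder epicentre aggregation.

# internal: the linear operator d -> D as a matrix, so spun maps can be
# propagated with a single matrix-vector product
neighbour_operator <- function(sc, fc = NULL, abs_fc = FALSE) {
  w <- sc$weights
  if (!is.null(fc)) {
    if (fc$n_regions != sc$n_regions)
      stop("functional network misaligned with the structural network")
    f <- fc$weights
    if (abs_fc) f <- abs(f)
    w <- w * f
  }
  n_i <- rowSums(sc$weights > 0)
  list(op = w / ifelse(n_i == 0, 1, n_i), isolated = n_i == 0)
}

#' Mean neighbour abnormality
#'
#' For each region i, the connectivity-weighted mean abnormality of its
#' structurally connected neighbours,
#' D_i = (1/N_i) sum_{j != i} d_j * SC_ij, with N_i the number of regions
#' structurally connected to i. When a functional network is supplied each
#' neighbour is additionally weighted by its functional connection,
#' D_i = (1/N_i) sum_{j != i} d_j * SC_ij * FC_ij. The abnormality map
#' must be oriented so larger values mean more abnormal. Isolated regions
#' are masked with a warning.
#'
#' @param map abnormality `region_map` (larger = more abnormal).
#' @param sc structural `network`.
#' @param parc the aligned `parcellation`.
#' @param fc optional functional `network`.
#' @param abs_fc use absolute FC weights instead of signed (default
#'   signed, as printed).
#' @return A `region_map` of neighbour abnormality.
#' @export
neighbour_abnormality <- function(map, sc, parc, fc = NULL, abs_fc = FALSE) {
  stopifnot(inherits(map, "region_map"), inherits(sc, "network"))
  if (map$n_regions != sc$n_regions) stop("map and network are misaligned")
  if (!map$larger_more_abnormal)
    stop("map must be oriented larger = more abnormal (see flip_map())")
  nb <- neighbour_operator(sc, fc, abs_fc)
  vals <- drop(nb$op %*% map$values)
  if (any(nb$isolated)) {
    warning(sprintf("%d isolated region(s) masked in neighbour abnormality",
                    sum(nb$isolated)))
    vals[nb$isolated] <- NA_real_
  }
  region_map(vals, parc, name = paste0(map$name, "_neighbour"),
             mask = nb$isolated)
}

#' Flip the orientation of an abnormality map
#'
#' Negates the values and toggles the orientation flag; convenience for
#' maps supplied as thinning-negative effect sizes.
#'
#' @param map a `region_map`.
#' @return The flipped map.
#' @export
flip_map <- function(map) {
  stopifnot(inherits(map, "region_map"))
  map$values <- -map$values
  map$larger_more_abnormal <- !map$larger_more_abnormal
  map
}

#' Node-neighbour spreading correlation with spin significance
#'
#' The extent to which a disorder's cortical abnormality follows the
#' connectome: the Pearson correlation between regional abnormality d and
#' mean neighbour abnormality D. Significance is a two-sided spin test:
#' the abnormality map is spun, neighbour abnormality is recomputed per
#' permutation, and the null correlations are compared to the observed
#' one, controlling for spatial autocorrelation.
#'
#' @param map abnormality `region_map` (larger = more abnormal).
#' @param sc structural `network`.
#' @param parc the aligned `parcellation`.
#' @param spins spin `null_ensemble` on the same parcellation.
#' @param fc optional functional `network` (SC+FC variant).
#' @param abs_fc use absolute FC weights.
#' @return A `spread_result`: node_values, neighbour_values, r, p_spin,
#'   null correlations, variant ("SC" or "SCFC").
#' @export
spreading_correlation <- function(map, sc, parc, spins, fc = NULL,
                                  abs_fc = FALSE) {
  stopifnot(inherits(spins, "null_ensemble"), spins$method == "spin")
  if (spins$n_regions != map$n_regions)
    stop("spin ensemble generated on a different parcellation")
  nb <- neighbour_operator(sc, fc, abs_fc)
  keep <- !nb$isolated
  d_vals <- map$values
  d_obs <- drop(nb$op %*% d_vals)
  if (stats::sd(d_obs[keep]) < 1e-12)
    stop("constant neighbour abnormality; correlation undefined")
  r_obs <- stats::cor(d_vals[keep], d_obs[keep])
  r_null <- vapply(seq_len(spins$n), function(k) {
    d_spun <- apply_spin(d_vals, spins, k)
    d_nb <- drop(nb$op %*% d_spun)
    if (stats::sd(d_nb[keep]) < 1e-12) return(NA_real_)
    stats::cor(d_spun[keep], d_nb[keep])
  }, numeric(1))
  structure(list(
    node_values = map,
    neighbour_values = region_map(ifelse(keep, d_obs, NA_real_), parc,
                                  name = paste0(map$name, "_neighbour"),
                                  mask = !keep),
    r = r_obs,
    p_spin = spin_pvalue(r_obs, r_null, sided = "two"),
    null_r = r_null,
    variant = if (is.null(fc)) "SC" else "SCFC"
  ), class = "spread_result")
}

#' @export
print.spread_result <- function(x, ...) {
  cat(sprintf("spread_result (%s): r = %.3f, p_spin = %.4f\n",
              x$variant, x$r, x$p_spin))
  invisible(x)
}

#' Epicentre likelihood
#'
#' Regions that are both highly abnormal and connected to highly abnormal
#' neighbours are candidate epicentres of a network-patterned disorder.
#' Node and neighbour abnormality are each ranked ascending (the most
#' abnormal region gets the highest rank, ties receive average ranks) and
#' the epicentre likelihood is the mean of the two ranks. Invariant under
#' any strictly increasing transform of the abnormality map.
#'
#' @param map abnormality `region_map` (larger = more abnormal).
#' @param sc structural `network`.
#' @param parc the aligned `parcellation`.
#' @param fc optional functional `network`.
#' @param abs_fc use absolute FC weights.
#' @return An `epicentre_map`: likelihood (`region_map`), node_rank,
#'   neighbour_rank.
#' @export
epicentre_likelihood <- function(map, sc, parc, fc = NULL, abs_fc = FALSE) {
  nb_map <- neighbour_abnormality(map, sc, parc, fc = fc, abs_fc = abs_fc)
  node_rank <- rank(map$values, ties.method = "average")
  neighbour_rank <- rank(nb_map$values, ties.method = "average",
                         na.last = "keep")
  lik <- (node_rank + neighbour_rank) / 2
  structure(list(
    likelihood = region_map(lik, parc, name = paste0(map$name, "_epicentre"),
                            mask = is.na(lik)),
    node_rank = node_rank,
    neighbour_rank = neighbour_rank
  ), class = "epicentre_map")
}

#' Aggregate epicentre likelihood maps across disorders
#'
#' Combines per-disorder epicentre likelihood maps into a single
#' cross-disorder map. Maps inside a merge group (e.g. left and right
#' variants of the same disorder) are first averaged into one map so they
#' do not bias the aggregate. Aggregation is the elementwise median or
#' mean of likelihoods, or the frequency with which each region falls in
#' the top half of a map's likelihoods. Callers should include only
#' disorders whose spreading correlation is significant.
#'
#' @param epimaps list of `epicentre_map` objects (or `region_map`
#'   likelihoods) on a common parcellation.
#' @param parc the aligned `parcellation`.
#' @param merge_groups optional list of integer index vectors; each group
#'   is averaged into a single map before aggregation.
#' @param method "median", "mean", or "frequency".
#' @return A `region_map` of aggregated epicentre likelihood.
#' @export
aggregate_epicentres <- function(epimaps, parc,
                                 merge_groups = NULL,
                                 method = c("median", "mean", "frequency")) {
  method <- match.arg(method)
  if (length(epimaps) == 0) stop("no epicentre maps supplied")
  vals <- lapply(epimaps, function(m) {
    if (inherits(m, "epicentre_map")) m$likelihood$values
    else if (inherits(m, "region_map")) m$values
    else stop("epimaps must be epicentre_map or region_map objects")
  })
  if (length(unique(lengths(vals))) != 1) stop("epicentre maps are misaligned")
  if (!is.null(merge_groups)) {
    merged <- lapply(merge_groups, function(g)
      Reduce(`+`, vals[g]) / length(g))
    vals <- c(vals[-unlist(merge_groups)], merged)
  }
  mat <- do.call(cbind, vals)
  out <- switch(method,
    median = apply(mat, 1, stats::median),
    mean = rowMeans(mat),
    frequency = rowSums(apply(mat, 2, function(v)
      v >= stats::median(v))))
  region_map(out, parc, name = paste0("epicentre_", method))
}
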