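# The seven connectomic predictors, computed on a weighted structural
# network. Path-based measures use the length transform length = 1/weight.

#' Node strength
#'
#' Sum of the weights of the edges attached to each region (degree for a
#' binary network).
#'
#' @param net a `network`.
#' @param parc the aligned `parcellation`.
#' @return A `region_map`.
#' @export
strength <- function(net, parc) {
  stopifnot(inherits(net, "network"))
  region_map(rowSums(net$weights), parc, name = "strength")
}

#' Betweenness centrality
#'
#' Fraction of all shortest paths between pairs of other regions that
#' traverse each region, on lengths 1/weight, normalised by
#' (N-1)(N-2) (ordered pairs) so values lie in [0, 1].
#'
#' @param net a connected `network`.
#' @param parc the aligned `parcellation`.
#' @return A `region_map`.
#' @export
betweenness <- function(net, parc) {
  stopifnot(inherits(net, "network"))
  check_connected(net, "betweenness")
  g <- as_igraph_lengths(net)
  b <- igraph::betweenness(g, directed = FALSE)
  n <- net$n_regions
  region_map(2 * b / ((n - 1) * (n - 2)), parc, name = "betweenness")
}

#' Closeness (mean shortest-path distance)
#'
#' Mean shortest-path distance from each region to every other region on
#' lengths 1/weight. Note the orientation: smaller values mean a more
#' central region.
#'
#' @param net a connected `network`.
#' @param parc the aligned `parcellation`.
#' @return A `region_map`.
#' @export
closeness <- function(net, parc) {
  stopifnot(inherits(net, "network"))
  check_connected(net, "closeness")
  g <- as_igraph_lengths(net)
  d <- igraph::distances(g)
  n <- net$n_regions
  region_map(rowSums(d) / (n - 1), parc, name = "closeness")
}

#' Mean Euclidean distance to all other regions
#'
#' How spatially peripheral a region is: the mean Euclidean distance from
#' its centroid to every other centroid.
#'
#' @param parc a `parcellation`.
#' @return A `region_map`.
#' @export
mean_euclidean_distance <- function(parc) {
  d <- centroid_distances(parc)
  n <- parc$n_regions
  region_map(rowSums(d) / (n - 1), parc, name = "euclidean_distance")
}

#' Participation coefficient
#'
#' Diversity of a region's connections across modules:
#' PC_i = 1 - sum_s (k_is / k_i)^2, with k_is the summed weight from
#' region i into module s. Isolated regions get 0.
#'
#' @param net a `network`.
#' @param parc the aligned `parcellation`.
#' @param assignments integer module label per region; defaults to the
#'   parcellation's `network_id`.
#' @return A `region_map`.
#' @export
participation_coefficient <- function(net, parc, assignments = parc$network_id) {
  stopifnot(inherits(net, "network"))
  if (is.null(assignments)) stop("every region needs a module assignment")
  assignments <- as.integer(assignments)
  if (length(assignments) != net$n_regions || anyNA(assignments))
    stop("every region needs a module assignment")
  w <- net$weights
  k <- rowSums(w)
  mods <- sort(unique(assignments))
  k_is <- vapply(mods, function(s)
    rowSums(w[, assignments == s, drop = FALSE]), numeric(net$n_regions))
  pc <- 1 - rowSums((k_is / ifelse(k == 0, 1, k))^2)
  pc[k == 0] <- 0
  region_map(pc, parc, name = "participation")
}

#' Weighted clustering coefficient
#'
#' Onnela-form weighted clustering: weights are normalised by the network
#' maximum, triangle intensity is the cube-root geometric mean of its three
#' normalised weights, and each region's coefficient is the average
#' intensity over its k(k-1) ordered neighbour pairs. Regions with binary
#' degree < 2 get 0. On a binary network this reduces to the fraction of
#' closed triangles.
#'
#' @param net a `network`.
#' @param parc the aligned `parcellation`.
#' @return A `region_map`.
#' @export
clustering <- function(net, parc) {
  stopifnot(inherits(net, "network"))
  w <- net$weights
  mx <- max(w)
  if (mx == 0) return(region_map(numeric(net$n_regions), parc,
                                 name = "clustering"))
  cw <- (w / mx)^(1 / 3)
  cyc <- diag(cw %*% cw %*% cw)
  k <- rowSums(w > 0)
  denom <- k * (k - 1)
  vals <- ifelse(denom > 0, cyc / denom, 0)
  region_map(vals, parc, name = "clustering")
}

#' Mean first passage time
#'
#' Expected number of steps for a discrete-time random walker (transition
#' probabilities proportional to edge weight) to first reach region j from
#' region i, computed from the fundamental matrix of the chain; the
#' stationary distribution is proportional to strength. The per-region map
#' averages over all targets j != i.
#'
#' @param net a connected `network` with positive weights.
#' @param parc the aligned `parcellation`.
#' @return A `region_map` with the full MFPT matrix attached as attribute
#'   `mfpt_matrix` (rows = start, columns = target).
#' @export
mean_first_passage_time <- function(net, parc) {
  stopifnot(inherits(net, "network"))
  check_connected(net, "mean first passage time")
  w <- net$weights
  s <- rowSums(w)
  p <- w / s
  pi_st <- s / sum(s)
  n <- nrow(w)
  z <- solve(diag(n) - p + matrix(pi_st, n, n, byrow = TRUE))
  # MFPT(i -> j) = (Z_jj - Z_ij) / pi_j
  mfpt <- (matrix(diag(z), n, n, byrow = TRUE) - z) /
    matrix(pi_st, n, n, byrow = TRUE)
  diag(mfpt) <- 0
  map <- region_map(rowSums(mfpt) / (n - 1), parc, name = "mfpt")
  attr(map, "mfpt_matrix") <- mfpt
  map
}

#' Assemble the connectomic predictor table
#'
#' Computes the seven connectomic predictors in fixed order — strength,
#' betweenness, closeness, Euclidean distance, participation coefficient,
#' clustering, mean first passage time — and z-scores every column.
#'
#' @param net a connected structural `network`.
#' @param parc the aligned `parcellation` (must carry `network_id` for the
#'   participation coefficient).
#' @return A standardized `predictor_table` with family "connectomic".
#' @export
connectivity_predictors <- function(net, parc) {
  cols <- cbind(
    strength = strength(net, parc)$values,
    betweenness = betweenness(net, parc)$values,
    closeness = closeness(net, parc)$values,
    euclidean_distance = mean_euclidean_distance(parc)$values,
    participation = participation_coefficient(net, parc)$values,
    clustering = clustering(net, parc)$values,
    mfpt = mean_first_passage_time(net, parc)$values
  )
  zscore_columns(predictor_table(cols, parc, family = "connectomic"))
}
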