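# Spatial null models: hemisphere-aware spin permutations of parcellated
# maps, and degree- and edge-length-preserving rewired networks.

# uniform random rotation: QR of a Gaussian matrix, sign-fixed so columns
# follow the Haar measure, determinant forced to +1
random_rotation <- function() {
  qrd <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  q <- q %*% diag(sign(diag(qr.R(qrd))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a spin-permutation ensemble
#'
#' Spatial-autocorrelation-preserving permutations of parcellated maps.
#' Per repetition a uniform random 3D rotation is applied to one
#' hemisphere's unit-sphere coordinates and its mirror image (conjugation
#' by x-reflection) to the other, and each region is reassigned the value
#' of the nearest rotated region within its own hemisphere. The
#' reassignment is nearest-neighbour, not forced to a bijection, so a
#' source region's value may be duplicated or dropped; no value ever
#' crosses hemispheres. Masked regions take the nearest unmasked source.
#'
#' @param parc a `parcellation` with sphere coordinates.
#' @param n number of permutations.
#' @param seed integer seed.
#' @param mask optional logical vector of regions excluded as sources.
#' @return A `null_ensemble` with method "spin" and an n x N integer
#'   matrix of source indices (`permutations[r, i]` is the region whose
#'   value region i takes in repetition r).
#' @export
generate_spins <- function(parc, n = 1000, seed = 1L, mask = NULL) {
  stopifnot(inherits(parc, "parcellation"))
  if (is.null(parc$sphere_xyz)) stop("parcellation has no sphere coordinates")
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    stopifnot(length(mask) == parc$n_regions)
    if (all(mask)) stop("mask excludes every source region")
  } else mask <- rep(FALSE, parc$n_regions)
  xyz <- parc$sphere_xyz
  is_l <- parc$hemisphere == "L"
  idx_l <- which(is_l); idx_r <- which(!is_l)
  mirror <- diag(c(-1, 1, 1))
  set.seed(seed)
  perms <- matrix(0L, n, parc$n_regions)
  for (r in seq_len(n)) {
    rot <- random_rotation()
    rot_m <- mirror %*% rot %*% mirror    # mirrored rotation for the other side
    for (h in list(list(idx = idx_l, rot = rot),
                   list(idx = idx_r, rot = rot_m))) {
      src <- h$idx
      rotated <- xyz[src, , drop = FALSE] %*% t(h$rot)
      # distance from each original region to each rotated source
      d2 <- outer(rowSums(xyz[src, , drop = FALSE]^2),
                  rowSums(rotated^2), "+") -
        2 * xyz[src, , drop = FALSE] %*% t(rotated)
      d2[, mask[src]] <- Inf                 # masked sources never assigned
      perms[r, src] <- src[apply(d2, 1, which.min)]
    }
  }
  structure(list(method = "spin", permutations = perms, n = n, seed = seed,
                 n_regions = parc$n_regions,
                 hemisphere = parc$hemisphere),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("null_ensemble (%s): %d members, %d regions, seed %d\n",
              x$method, if (x$method == "spin") x$n else length(x$networks),
              x$n_regions, x$seed))
  invisible(x)
}

#' Permutation p-value
#'
#' Add-one permutation estimator: p = (1 + #{nulls at least as extreme as
#' the observed value}) / (n_nulls + 1). Two-sided compares absolute
#' values; one-sided counts nulls >= observed.
#'
#' @param observed observed statistic.
#' @param nulls numeric vector of null statistics.
#' @param sided "two" or "one".
#' @return p-value in (0, 1].
#' @export
spin_pvalue <- function(observed, nulls, sided = c("two", "one")) {
  sided <- match.arg(sided)
  nulls <- nulls[!is.na(nulls)]
  if (length(nulls) == 0) stop("empty null distribution")
  hits <- if (sided == "two") sum(abs(nulls) >= abs(observed))
          else sum(nulls >= observed)
  (1 + hits) / (length(nulls) + 1)
}

#' Apply a spin permutation to a vector of region values
#'
#' @param values numeric vector aligned to the ensemble's parcellation.
#' @param spins a spin `null_ensemble`.
#' @param r repetition index.
#' @return Permuted vector.
#' @export
apply_spin <- function(values, spins, r) {
  stopifnot(spins$method == "spin", length(values) == spins$n_regions)
  values[spins$permutations[r, ]]
}

#' Generate degree- and edge-length-preserving rewired networks
#'
#' Null connectomes preserving the empirical network's density, degree
#' sequence, and edge-length distribution (up to bin resolution). Edges
#' are binned by centroid Euclidean distance; within each bin, random
#' pairs of edges are double-edge swapped ((a,b)+(c,d) -> (a,d)+(c,b)),
#' a swap being accepted only when both new edges are absent, create no
#' self-loop, and fall in the same distance bin. Weights travel with
#' their edges. Bins with fewer than two edges are skipped with a
#' warning.
#'
#' @param sc structural `network` (binary or weighted).
#' @param parc the aligned `parcellation`.
#' @param n_bins number of distance bins, or "auto" =
#'   round(sqrt(edge count)).
#' @param n_swaps attempted swaps per ensemble member (default 10000).
#' @param n_ensembles number of rewired networks.
#' @param seed integer seed.
#' @return A `null_ensemble` with method "rewire" and `networks`, a list
#'   of rewired `network` objects.
#' @export
rewire_preserving <- function(sc, parc, n_bins = "auto", n_swaps = 10000,
                              n_ensembles = 100, seed = 1L) {
  stopifnot(inherits(sc, "network"))
  n <- sc$n_regions
  check_aligned(n, parc, "network")
  ut <- which(upper.tri(sc$weights) & sc$weights > 0)
  m <- length(ut)
  if (m < 2) stop("network has fewer than two edges")
  if (identical(n_bins, "auto")) n_bins <- max(1L, round(sqrt(m)))
  n_bins <- as.integer(n_bins)
  d <- centroid_distances(parc)
  lens <- d[ut]
  breaks <- seq(min(lens), max(lens), length.out = n_bins + 1)
  dist_bin <- matrix(findInterval(d, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), n, n)
  idx <- arrayInd(ut, c(n, n))
  edge_bin <- dist_bin[ut]
  small <- table(factor(edge_bin, levels = seq_len(n_bins))) < 2
  if (any(small))
    warning(sprintf("%d distance bin(s) hold fewer than two edges and cannot be rewired",
                    sum(small)))
  weights <- sc$weights[ut]
  set.seed(seed)
  nets <- lapply(seq_len(n_ensembles), function(e) {
    new_edges <- rewire_swaps(cbind(idx[, 1], idx[, 2]),
                              as.integer(edge_bin), dist_bin,
                              as.integer(n_swaps))
    w <- matrix(0, n, n)
    w[new_edges] <- weights
    w[new_edges[, c(2, 1), drop = FALSE]] <- weights
    network(w, parc, kind = sc$kind)
  })
  structure(list(method = "rewire", networks = nets, seed = seed,
                 n_regions = n,
                 parameters = list(n_bins = n_bins, n_swaps = n_swaps)),
            class = "null_ensemble")
}
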