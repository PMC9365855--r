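#' Construct a connectivity network
#'
#' A square symmetric weight matrix aligned to a parcellation, with zero
#' diagonal. Structural networks (streamline-derived connectomes) must be
#' nonnegative; functional networks (BOLD correlation) may carry signed
#' weights.
#'
#' @param weights square numeric matrix.
#' @param parc aligned `parcellation`.
#' @param kind "structural" or "functional".
#' @param symmetrize_tol asymmetry up to this tolerance is silently removed
#'   by averaging with the transpose; larger asymmetry is an error.
#' @return Object of class `network`.
#' @export
network <- function(weights, parc, kind = c("structural", "functional"),
                    symmetrize_tol = 1e-8) {
  kind <- match.arg(kind)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weight matrix must be square")
  check_aligned(nrow(weights), parc, "network")
  asym <- max(abs(weights - t(weights)))
  if (asym > symmetrize_tol)
    stop(sprintf("matrix asymmetry %.3g exceeds tolerance %.3g",
                 asym, symmetrize_tol))
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  if (kind == "structural" && any(weights < 0))
    stop("structural network has negative weights")
  dimnames(weights) <- list(parc$region_labels, parc$region_labels)
  structure(list(weights = weights, kind = kind, n_regions = nrow(weights)),
            class = "network")
}

#' @export
print.network <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] != 0)
  np <- x$n_regions * (x$n_regions - 1) / 2
  cat(sprintf("network (%s): %d regions, density %.3f\n",
              x$kind, x$n_regions, nz / np))
  invisible(x)
}

#' Binary density of a network
#'
#' Fraction of the n(n-1)/2 possible edges with nonzero weight.
#'
#' @param net a `network`.
#' @return Density in [0, 1].
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "network"))
  ut <- net$weights[upper.tri(net$weights)]
  mean(ut != 0)
}

#' Binarise a network
#'
#' @param net a `network`.
#' @return The network with all nonzero weights set to 1.
#' @export
binarize <- function(net) {
  stopifnot(inherits(net, "network"))
  net$weights <- (net$weights != 0) * 1
  net
}

# internal: igraph view of a network on lengths 1/w for path-based metrics
as_igraph_lengths <- function(net) {
  w <- net$weights
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::E(g)$weight <- 1 / igraph::E(g)$weight
  g
}

# internal: error if the network is disconnected, naming component sizes
check_connected <- function(net, op = "this operation") {
  g <- igraph::graph_from_adjacency_matrix(net$weights != 0,
                                           mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop(sprintf("%s requires a connected network; found %d components (sizes %s)",
                 op, comp$no, paste(comp$csize, collapse = ", ")))
  invisible(TRUE)
}
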