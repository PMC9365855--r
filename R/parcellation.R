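#' Construct a cortical parcellation
#'
#' A parcellation is the fixed frame of reference for every other object in
#' the package: an ordered set of uniquely labelled cortical regions, each
#' with a hemisphere flag, an anatomical centroid, and a unit-sphere
#' projection used by the spin test. Regions are stored in canonical order:
#' left hemisphere first, then right, each hemisphere sorted by label.
#'
#' @param region_labels character vector of unique region labels.
#' @param hemisphere character vector of "L"/"R" flags, one per region.
#' @param centroid_xyz numeric matrix (regions x 3) of centroid coordinates
#'   in the same units used for inter-regional distances.
#' @param sphere_xyz numeric matrix (regions x 3) of unit-sphere projection
#'   coordinates; every row must have norm 1 (tolerance 1e-8). Defaults to
#'   row-normalised centroids.
#' @param network_id optional integer vector of module assignments.
#' @param parcel_size optional positive numeric vector of parcel sizes
#'   (e.g. voxel counts).
#' @return An object of class `parcellation`: a list with the validated,
#'   canonically ordered fields above and `n_regions`.
#' @export
parcellation <- function(region_labels, hemisphere, centroid_xyz,
                         sphere_xyz = NULL, network_id = NULL,
                         parcel_size = NULL) {
  region_labels <- as.character(region_labels)
  n <- length(region_labels)
  if (anyDuplicated(region_labels))
    stop("region labels must be unique")
  hemisphere <- as.character(hemisphere)
  if (length(hemisphere) != n || !all(hemisphere %in% c("L", "R")))
    stop("hemisphere must be 'L' or 'R', one per region")
  if (!all(c("L", "R") %in% hemisphere))
    stop("both hemispheres must be non-empty")
  centroid_xyz <- as.matrix(centroid_xyz)
  if (nrow(centroid_xyz) != n || ncol(centroid_xyz) != 3)
    stop("centroid_xyz must be an n x 3 matrix")
  if (is.null(sphere_xyz)) {
    nrm <- sqrt(rowSums(centroid_xyz^2))
    if (any(nrm == 0)) stop("cannot normalise a zero centroid onto the sphere")
    sphere_xyz <- centroid_xyz / nrm
  }
  sphere_xyz <- as.matrix(sphere_xyz)
  if (nrow(sphere_xyz) != n || ncol(sphere_xyz) != 3)
    stop("sphere_xyz must be an n x 3 matrix")
  if (any(abs(sqrt(rowSums(sphere_xyz^2)) - 1) > 1e-8))
    stop("sphere_xyz rows must have unit norm (tolerance 1e-8)")
  if (!is.null(network_id)) {
    network_id <- as.integer(network_id)
    if (length(network_id) != n || anyNA(network_id))
      stop("network_id must be an integer per region")
  }
  if (!is.null(parcel_size)) {
    parcel_size <- as.numeric(parcel_size)
    if (length(parcel_size) != n || any(!is.finite(parcel_size)) ||
        any(parcel_size <= 0))
      stop("parcel_size must be a positive number per region")
  }

  # canonical order: L then R, label-sorted within hemisphere
  ord <- order(match(hemisphere, c("L", "R")), region_labels)
  structure(list(
    region_labels = region_labels[ord],
    hemisphere = hemisphere[ord],
    centroid_xyz = centroid_xyz[ord, , drop = FALSE],
    sphere_xyz = sphere_xyz[ord, , drop = FALSE],
    network_id = if (is.null(network_id)) NULL else network_id[ord],
    parcel_size = if (is.null(parcel_size)) NULL else parcel_size[ord],
    n_regions = n
  ), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation: %d regions (%d L, %d R)%s\n",
              x$n_regions, sum(x$hemisphere == "L"),
              sum(x$hemisphere == "R"),
              if (is.null(x$network_id)) ""
              else sprintf(", %d networks", length(unique(x$network_id)))))
  invisible(x)
}

#' Pairwise Euclidean distances between region centroids
#'
#' @param parc a `parcellation`.
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
centroid_distances <- function(parc) {
  stopifnot(inherits(parc, "parcellation"))
  as.matrix(stats::dist(parc$centroid_xyz))
}

# internal: check an object length/size matches the parcellation
check_aligned <- function(n, parc, what = "object") {
  if (!inherits(parc, "parcellation")) stop("parc must be a parcellation")
  if (n != parc$n_regions)
    stop(sprintf("%s has %d regions but parcellation has %d",
                 what, n, parc$n_regions))
  invisible(TRUE)
}
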