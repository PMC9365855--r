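# Synthetic study generator: spherical parcellations, distance-dependent
# subject connectomes, coupled functional networks, spatially smooth
# molecular maps, and abnormality maps with planted linear or diffusion
# structure. All geometry lives on a unit sphere with mirrored hemispheres
# so the spin test is exact in-model.

#' Specification of a synthetic study
#'
#' Bundles the knobs shared by the synthetic generators. Defaults emulate
#' the scale of a 68-region cortical atlas with a 70-subject connectome
#' cohort at roughly a quarter binary density.
#'
#' @param n_per_hemisphere regions per hemisphere (>= 8).
#' @param n_subjects number of subject connectomes in the cohort.
#' @param target_density mean binary edge density in (0, 1).
#' @param distance_decay length scale of the exponential edge-probability
#'   decay, in the units of the centroid coordinates (unit sphere).
#' @param autocorr_length length scale of the spatial covariance kernel for
#'   smooth molecular maps.
#' @param noise_sd default observation noise for abnormality maps.
#' @param n_networks number of mirrored intrinsic networks.
#' @param seed integer seed.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(n_per_hemisphere = 34, n_subjects = 70,
                       target_density = 0.25, distance_decay = 1,
                       autocorr_length = 0.5, noise_sd = 0.1,
                       n_networks = 7, seed = 1L) {
  stopifnot(n_per_hemisphere >= 8, n_subjects >= 1,
            target_density > 0, target_density < 1,
            distance_decay > 0, autocorr_length > 0, noise_sd >= 0,
            n_networks >= 1)
  structure(list(n_per_hemisphere = as.integer(n_per_hemisphere),
                 n_subjects = as.integer(n_subjects),
                 target_density = target_density,
                 distance_decay = distance_decay,
                 autocorr_length = autocorr_length,
                 noise_sd = noise_sd,
                 n_networks = as.integer(n_networks),
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# quasi-uniform Fibonacci lattice on the x > 0 hemisphere of the unit sphere
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n)
  x <- (i - 0.5) / n                  # uniform in x <=> uniform in area
  phi <- (1 + sqrt(5)) / 2
  theta <- 2 * pi * i * phi
  r <- sqrt(pmax(0, 1 - x^2))
  cbind(x = x, y = r * cos(theta), z = r * sin(theta))
}

#' Generate a mirrored spherical parcellation
#'
#' Places regions quasi-uniformly on two unit hemispheres mirrored across
#' the midline (x = 0): the right hemisphere is a Fibonacci lattice on the
#' x > 0 half-sphere and the left hemisphere its x-negated mirror. Sphere
#' projections equal the (already unit-norm) centroids. Network labels are
#' assigned by the nearest of `n_networks` seed points, shared between
#' hemispheres by mirroring, so every network is bilateral.
#'
#' @param spec a `synth_spec`.
#' @return A `parcellation` with network assignments and parcel sizes.
#' @export
make_parcellation <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  n <- spec$n_per_hemisphere
  right <- fibonacci_hemisphere(n)
  left <- right
  left[, 1] <- -left[, 1]
  xyz <- rbind(left, right)
  hemi <- rep(c("L", "R"), each = n)
  labels <- sprintf("%s_region_%02d", hemi, rep(seq_len(n), 2))

  k <- spec$n_networks
  seeds_r <- fibonacci_hemisphere(k)
  assign_r <- apply(right, 1, function(p)
    which.min(colSums((t(seeds_r) - p)^2)))
  network_id <- c(assign_r, assign_r)  # mirrored seeds => same labels

  set.seed(spec$seed)
  parcel_size <- round(exp(stats::rnorm(2 * n, mean = log(800), sd = 0.4)))

  parcellation(labels, hemi, xyz, sphere_xyz = xyz,
               network_id = network_id, parcel_size = parcel_size)
}

#' Generate a cohort of subject structural connectomes
#'
#' Each subject's binary edges are sampled independently with probability
#' proportional to exp(-distance / decay), calibrated so the expected
#' binary density equals `target_density`; edge weights are log-normal.
#' Emulates the geometry-dependence of streamline tractography cohorts.
#'
#' @param parc a `parcellation`.
#' @param spec a `synth_spec`.
#' @return List of structural `network` objects, one per subject.
#' @export
make_subject_connectomes <- function(parc, spec) {
  stopifnot(inherits(parc, "parcellation"), inherits(spec, "synth_spec"))
  d <- centroid_distances(parc)
  ut <- upper.tri(d)
  decay_term <- exp(-d[ut] / spec$distance_decay)
  scale <- spec$target_density / mean(decay_term)
  p <- scale * decay_term
  if (any(p > 1))
    stop("infeasible target density: calibrated edge probability exceeds 1")
  n <- parc$n_regions
  set.seed(spec$seed)
  lapply(seq_len(spec$n_subjects), function(s) {
    present <- stats::runif(length(p)) < p
    w <- numeric(length(p))
    w[present] <- stats::rlnorm(sum(present), meanlog = 0, sdlog = 1)
    m <- matrix(0, n, n)
    m[ut] <- w
    m <- m + t(m)
    network(m, parc, kind = "structural")
  })
}

# communicability of a strength-normalised adjacency matrix
sc_communicability <- function(w) {
  s <- rowSums(w)
  s[s == 0] <- 1
  d <- 1 / sqrt(s)
  as.matrix(Matrix::expm(Matrix::Matrix(d * t(d * w))))
}

# zero-mean Gaussian-process draws with covariance exp(-dist/length)
gp_draws <- function(dist_mat, length_scale, n_draws) {
  k <- exp(-dist_mat / length_scale)
  diag(k) <- diag(k) + 1e-8
  l <- t(chol(k))
  l %*% matrix(stats::rnorm(nrow(k) * n_draws), nrow(k), n_draws)
}

#' Generate a functional network coupled to a structural network
#'
#' Builds FC as `coupling` times the z-scored communicability of the
#' strength-normalised SC plus `1 - coupling` times spatially smooth noise,
#' symmetrised, rescaled to [-1, 1], diagonal zeroed. At coupling 1 the FC
#' is a monotone image of SC communicability; at coupling 0 it is
#' independent of the SC.
#'
#' @param sc structural `network`.
#' @param parc the aligned `parcellation` (geometry for the smooth noise).
#' @param coupling SC-FC coupling in [0, 1].
#' @param seed integer seed.
#' @return A functional `network`.
#' @export
make_fc <- function(sc, parc, coupling = 0.5, seed = 1L) {
  stopifnot(inherits(sc, "network"), coupling >= 0, coupling <= 1)
  n <- sc$n_regions
  comm <- sc_communicability(sc$weights)
  ut <- upper.tri(comm)
  set.seed(seed)
  d <- centroid_distances(parc)
  k <- exp(-d / 0.5)
  diag(k) <- diag(k) + 1e-8
  l <- t(chol(k))
  # zero-mean matrix-variate field, smooth in both indices, then symmetrised
  raw <- l %*% matrix(stats::rnorm(n * n), n, n) %*% t(l)
  smooth_noise <- (raw + t(raw)) / 2
  z <- function(v) (v - mean(v)) / stats::sd(v)
  mix <- coupling * z(comm[ut]) + (1 - coupling) * z(smooth_noise[ut])
  mix <- mix / max(abs(mix))
  m <- matrix(0, n, n)
  m[ut] <- mix
  m <- m + t(m)
  network(m, parc, kind = "functional")
}

#' Generate spatially autocorrelated molecular maps
#'
#' Draws `n_maps` columns from a zero-mean Gaussian process on the region
#' centroids with covariance exp(-distance / autocorr_length), then
#' z-scores each column. Stands in for empirical molecular annotation maps
#' (gradients, metabolism, myelination), whose dominant statistical feature
#' at parcel resolution is spatial autocorrelation.
#'
#' @param parc a `parcellation`.
#' @param n_maps number of maps (columns).
#' @param autocorr_length kernel length scale (unit-sphere units).
#' @param seed integer seed.
#' @param family family tag for the resulting table.
#' @return A standardized `predictor_table`.
#' @export
make_smooth_maps <- function(parc, n_maps = 7, autocorr_length = 0.5,
                             seed = 1L, family = "molecular") {
  stopifnot(inherits(parc, "parcellation"), n_maps >= 1, autocorr_length > 0)
  set.seed(seed)
  d <- centroid_distances(parc)
  draws <- gp_draws(d, autocorr_length, n_maps)
  colnames(draws) <- sprintf("map_%02d", seq_len(n_maps))
  zscore_columns(predictor_table(draws, parc, family = family))
}

#' Generate an abnormality map with planted linear structure
#'
#' Forward model for the multilinear analysis: y = X beta + noise with
#' i.i.d. Gaussian noise. The planted population R^2,
#' beta' Sigma beta / (beta' Sigma beta + noise_sd^2) with Sigma the
#' empirical predictor covariance, is attached as an attribute.
#'
#' @param predictors a standardized `predictor_table` (the X).
#' @param parc the aligned `parcellation`.
#' @param betas numeric coefficient per predictor.
#' @param noise_sd noise standard deviation.
#' @param seed integer seed.
#' @return A `region_map` with attributes `planted_r2` and `betas`.
#' @export
make_abnormality_linear <- function(predictors, parc, betas, noise_sd,
                                    seed = 1L) {
  stopifnot(inherits(predictors, "predictor_table"),
            length(betas) == ncol(predictors$matrix), noise_sd >= 0)
  x <- predictors$matrix
  set.seed(seed)
  y <- drop(x %*% betas) + stats::rnorm(nrow(x), sd = noise_sd)
  sigma <- stats::cov(x)
  signal <- drop(t(betas) %*% sigma %*% betas)
  map <- region_map(y, parc, name = "abnormality_linear")
  attr(map, "planted_r2") <- if (signal + noise_sd^2 == 0) 0
                             else signal / (signal + noise_sd^2)
  attr(map, "betas") <- betas
  map
}

#' Noise level for a target planted population R^2
#'
#' Inverts the planted-R^2 relation of [make_abnormality_linear()]:
#' noise_sd = sqrt(beta' Sigma beta (1 - R2) / R2).
#'
#' @param predictors standardized `predictor_table`.
#' @param betas coefficient vector.
#' @param r2 target population R^2 in (0, 1).
#' @return Noise standard deviation.
#' @export
noise_for_r2 <- function(predictors, betas, r2) {
  stopifnot(r2 > 0, r2 < 1)
  sigma <- stats::cov(predictors$matrix)
  signal <- drop(t(betas) %*% sigma %*% betas)
  sqrt(signal * (1 - r2) / r2)
}

#' Generate an abnormality map by diffusion from a planted epicentre
#'
#' Forward model for the network-spreading analysis: the noiseless map is
#' the resolvent spread (I - alpha W)^{-1} e from the epicentre indicator
#' e, with W the row-normalised structural connectome, passed through a
#' square-root saturation (which preserves the indicator limit at
#' alpha -> 0, the location of the maximum, and all rank structure, while
#' keeping the seed's delta component from dominating the map's variance),
#' scaled to unit standard deviation so `noise_sd` reads as a relative
#' noise level, and finally perturbed with Gaussian noise. This is the
#' simplest saturating linear spreading process consistent with
#' trans-synaptic propagation; it serves as a test harness with a known
#' epicentre, not as a mechanistic claim.
#'
#' @param sc structural `network`.
#' @param parc aligned `parcellation`.
#' @param epicentre_index planted epicentre (1-based region index).
#' @param alpha spread strength in (0, 1); must stay below the reciprocal
#'   spectral radius of the row-normalised SC (which is 1).
#' @param noise_sd noise standard deviation.
#' @param seed integer seed.
#' @return A `region_map` (larger = more abnormal) with attribute
#'   `epicentre_index`.
#' @export
make_abnormality_diffusion <- function(sc, parc, epicentre_index,
                                       alpha = 0.4, noise_sd = 0.1,
                                       seed = 1L) {
  stopifnot(inherits(sc, "network"), alpha > 0)
  n <- sc$n_regions
  stopifnot(epicentre_index >= 1, epicentre_index <= n)
  s <- rowSums(sc$weights)
  if (any(s == 0)) stop("diffusion requires no isolated regions")
  w_hat <- sc$weights / s
  if (alpha >= 1)
    stop("alpha must be below the reciprocal spectral radius (1) of the row-normalised SC")
  e <- numeric(n)
  e[epicentre_index] <- 1
  y <- sqrt(solve(diag(n) - alpha * w_hat, e))
  y <- y / stats::sd(y)
  set.seed(seed)
  y <- y + stats::rnorm(n, sd = noise_sd)
  map <- region_map(y, parc, name = "abnormality_diffusion")
  attr(map, "epicentre_index") <- as.integer(epicentre_index)
  map
}
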