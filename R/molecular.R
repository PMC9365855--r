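# Derived molecular predictors computed from raw annotation matrices:
# principal-component gradients, excitatory:inhibitory receptor ratio, and
# the glycolytic index (residual of glucose on oxygen metabolism).

#' First principal component of an annotation matrix
#'
#' Z-scores every feature column and returns the first principal-component
#' scores of the region x feature matrix — the dominant spatial gradient of
#' the annotation (e.g. the gene-expression or receptor-density gradient).
#' The sign is fixed so the loading vector sums to a nonnegative value
#' (ties broken by a nonnegative first loading), making the output
#' deterministic; downstream regression fits are sign-invariant.
#'
#' @param ann an `annotation_matrix`.
#' @param parc the aligned `parcellation`.
#' @return A `region_map` of PC1 scores with attributes `var_explained`
#'   (fraction of variance) and `loadings`.
#' @export
pc1_gradient <- function(ann, parc) {
  stopifnot(inherits(ann, "annotation_matrix"))
  m <- ann$matrix
  if (ncol(m) < 2) stop("need at least two features")
  sds <- apply(m, 2, stats::sd)
  if (any(sds < 1e-12))
    stop("constant feature(s): ",
         paste(ann$feature_names[sds < 1e-12], collapse = ", "))
  z <- scale(m)
  p <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  load1 <- p$rotation[, 1]
  s <- sum(load1)
  flip <- if (abs(s) > 1e-12) sign(s) else if (load1[1] >= 0) 1 else -1
  scores <- p$x[, 1] * flip
  map <- region_map(scores, parc, name = "pc1_gradient")
  attr(map, "var_explained") <- p$sdev[1]^2 / sum(p$sdev^2)
  attr(map, "loadings") <- load1 * flip
  map
}

#' Excitatory:inhibitory receptor ratio
#'
#' Per region, the ratio of the summed z-scored excitatory receptor
#' densities to the summed z-scored inhibitory densities. Features are
#' selected by their class labels. Regions where the denominator magnitude
#' falls below `tol` are masked (the ratio is undefined there) and a
#' warning reports them. The aggregation across features within a class is
#' exposed via `aggregate` ("sum" or "mean"; both give identical ratios
#' when class sizes are equal).
#'
#' @param ann an `annotation_matrix` with `class_labels`.
#' @param parc the aligned `parcellation`.
#' @param excitatory,inhibitory class labels identifying the two sets.
#' @param aggregate "sum" or "mean" within class.
#' @param tol denominator-magnitude threshold below which a region is
#'   masked.
#' @return A `region_map` (masked where undefined).
#' @export
ei_ratio <- function(ann, parc, excitatory = "excitatory",
                     inhibitory = "inhibitory",
                     aggregate = c("sum", "mean"), tol = 1e-10) {
  stopifnot(inherits(ann, "annotation_matrix"))
  aggregate <- match.arg(aggregate)
  if (is.null(ann$class_labels)) stop("annotation matrix has no class labels")
  e_idx <- which(ann$class_labels == excitatory)
  i_idx <- which(ann$class_labels == inhibitory)
  if (length(e_idx) == 0) stop("empty excitatory class")
  if (length(i_idx) == 0) stop("empty inhibitory class")
  z <- scale(ann$matrix)
  agg <- if (aggregate == "sum") rowSums else rowMeans
  num <- agg(z[, e_idx, drop = FALSE])
  den <- agg(z[, i_idx, drop = FALSE])
  mask <- abs(den) < tol
  vals <- num / den
  vals[mask] <- NA_real_
  if (any(mask))
    warning(sprintf("E:I ratio undefined (|denominator| < %g) at %d region(s); masked",
                    tol, sum(mask)))
  region_map(vals, parc, name = "ei_ratio", mask = mask)
}

#' Glycolytic index
#'
#' Residual of glucose metabolism regressed on oxygen metabolism (ordinary
#' least squares with intercept). Larger values indicate more aerobic
#' glycolysis — glucose use in excess of what oxidative metabolism
#' predicts.
#'
#' @param glucose `region_map` of glucose metabolism.
#' @param oxygen `region_map` of oxygen metabolism on the same
#'   parcellation.
#' @param parc the aligned `parcellation`.
#' @return A `region_map` of residuals (they sum to zero and are
#'   uncorrelated with the oxygen map).
#' @export
glycolytic_index <- function(glucose, oxygen, parc) {
  stopifnot(inherits(glucose, "region_map"), inherits(oxygen, "region_map"))
  if (glucose$n_regions != oxygen$n_regions)
    stop("glucose and oxygen maps are misaligned")
  if (stats::sd(oxygen$values) < 1e-12) stop("constant oxygen map")
  fit <- stats::lm(glucose$values ~ oxygen$values)
  region_map(stats::residuals(fit), parc, name = "glycolytic_index")
}
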