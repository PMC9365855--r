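#' Construct a region map
#'
#' One real value per region, aligned to a parcellation. Used for cortical
#' abnormality maps (case-vs-control Cohen's d per region), molecular maps,
#' epicentre likelihoods, and any other per-region statistic.
#'
#' @param values numeric vector, one value per region in parcellation order.
#' @param parc the `parcellation` the values are aligned to.
#' @param name short name for the map.
#' @param larger_more_abnormal logical; for abnormality maps, declares that
#'   larger values mean more abnormal tissue (the orientation assumed by the
#'   spreading and epicentre operations).
#' @param mask optional logical vector marking regions whose value is
#'   undefined; masked entries may be NA.
#' @return Object of class `region_map`.
#' @export
region_map <- function(values, parc, name = "map",
                       larger_more_abnormal = TRUE, mask = NULL) {
  values <- as.numeric(values)
  check_aligned(length(values), parc, "region map")
  if (is.null(mask)) {
    if (anyNA(values)) stop("missing values require an explicit mask")
    mask <- rep(FALSE, length(values))
  } else {
    mask <- as.logical(mask)
    if (length(mask) != length(values)) stop("mask length mismatch")
    if (anyNA(values[!mask])) stop("NA outside the mask")
  }
  structure(list(values = values, name = name,
                 larger_more_abnormal = isTRUE(larger_more_abnormal),
                 mask = mask, n_regions = length(values)),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("region_map '%s': %d regions%s\n", x$name, x$n_regions,
              if (any(x$mask)) sprintf(" (%d masked)", sum(x$mask)) else ""))
  invisible(x)
}

#' Construct a predictor table
#'
#' A region x predictor matrix with named columns, used as the design matrix
#' of the multilinear abnormality models. Carries a family tag (molecular,
#' connectomic, or temporal) and a flag recording whether columns have been
#' z-scored.
#'
#' @param matrix numeric region x predictor matrix.
#' @param parc aligned `parcellation`.
#' @param column_names predictor names (defaults to existing colnames).
#' @param family one of "molecular", "connectomic", "temporal".
#' @param standardized logical; TRUE once columns are z-scored.
#' @return Object of class `predictor_table`.
#' @export
predictor_table <- function(matrix, parc, column_names = colnames(matrix),
                            family = c("molecular", "connectomic", "temporal"),
                            standardized = FALSE) {
  family <- match.arg(family)
  matrix <- as.matrix(matrix)
  check_aligned(nrow(matrix), parc, "predictor table")
  if (is.null(column_names) || length(column_names) != ncol(matrix))
    stop("column_names must name every predictor")
  if (anyDuplicated(column_names)) stop("predictor names must be unique")
  colnames(matrix) <- column_names
  if (isTRUE(standardized)) {
    sds <- apply(matrix, 2, stats::sd)
    if (any(sds < 1e-12))
      stop("constant column after standardization: ",
           paste(column_names[sds < 1e-12], collapse = ", "))
  }
  structure(list(matrix = matrix, column_names = column_names,
                 family = family, standardized = isTRUE(standardized),
                 n_regions = nrow(matrix)),
            class = "predictor_table")
}

#' @export
print.predictor_table <- function(x, ...) {
  cat(sprintf("predictor_table (%s): %d regions x %d predictors%s\n",
              x$family, x$n_regions, ncol(x$matrix),
              if (x$standardized) ", z-scored" else ""))
  invisible(x)
}

#' Z-score the columns of a predictor table
#'
#' Centres each column to mean 0 and scales to sample standard deviation 1,
#' as applied to both molecular and connectomic predictors before model
#' fitting. Idempotent.
#'
#' @param table a `predictor_table`.
#' @return The table with standardized columns and the flag set.
#' @export
zscore_columns <- function(table) {
  stopifnot(inherits(table, "predictor_table"))
  m <- table$matrix
  sds <- apply(m, 2, stats::sd)
  if (any(sds < 1e-12))
    stop("cannot z-score constant column: ",
         paste(table$column_names[sds < 1e-12], collapse = ", "))
  m <- scale(m)
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  table$matrix <- m
  colnames(table$matrix) <- table$column_names
  table$standardized <- TRUE
  table
}

# internal: z-score a plain numeric vector (sample SD)
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) stop("cannot z-score a constant vector")
  (x - mean(x)) / s
}

#' Construct an annotation matrix
#'
#' Region x feature matrix of raw molecular annotations (e.g. gene
#' expression or PET-derived receptor densities) from which derived
#' molecular predictors are computed. Features may carry class labels
#' (e.g. excitatory/inhibitory).
#'
#' @param matrix numeric region x feature matrix.
#' @param parc aligned `parcellation`.
#' @param feature_names unique feature names.
#' @param class_labels optional character vector of per-feature classes.
#' @return Object of class `annotation_matrix`.
#' @export
annotation_matrix <- function(matrix, parc, feature_names = colnames(matrix),
                              class_labels = NULL) {
  matrix <- as.matrix(matrix)
  check_aligned(nrow(matrix), parc, "annotation matrix")
  if (is.null(feature_names) || length(feature_names) != ncol(matrix))
    stop("feature_names must name every feature")
  if (anyDuplicated(feature_names)) stop("feature names must be unique")
  if (!is.null(class_labels) && length(class_labels) != ncol(matrix))
    stop("class_labels must have one entry per feature")
  colnames(matrix) <- feature_names
  structure(list(matrix = matrix, feature_names = feature_names,
                 class_labels = class_labels, n_regions = nrow(matrix)),
            class = "annotation_matrix")
}
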