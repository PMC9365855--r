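# Delimited-text readers and writers for region tables and dense matrices.
# Dialect: comma- or tab-delimited, auto-detected from the header line;
# region labels are case-sensitive exact strings.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab >= n_com && n_tab > 0) "\t" else if (n_com > 0) "," else "\t"
}

# align data-frame rows (first column = region labels) to parcellation order
align_rows <- function(df, parc, path) {
  labels <- as.character(df[[1]])
  dup <- labels[duplicated(labels)]
  if (length(dup))
    stop(sprintf("duplicate region label(s) in %s: %s", path,
                 paste(unique(dup), collapse = ", ")))
  extra <- setdiff(labels, parc$region_labels)
  if (length(extra))
    stop(sprintf("non-atlas row(s) in %s: %s", path,
                 paste(extra, collapse = ", ")))
  missing <- setdiff(parc$region_labels, labels)
  if (length(missing))
    stop(sprintf("region(s) missing from %s: %s", path,
                 paste(missing, collapse = ", ")))
  df[match(parc$region_labels, labels), , drop = FALSE]
}

#' Read a delimited region table
#'
#' Reads a delimited text table whose first column holds region labels and
#' whose remaining columns hold per-region values, reordering rows to the
#' parcellation's canonical order. Every parcellation region must appear
#' exactly once; unknown or missing labels are an error, never silently
#' dropped.
#'
#' @param path path to a comma- or tab-delimited file with a header row.
#' @param parc target `parcellation`.
#' @param family predictor family tag used when the table has more than one
#'   value column.
#' @return A `region_map` when the table has a single value column, else a
#'   `predictor_table`.
#' @export
read_region_table <- function(path, parc,
                              family = c("molecular", "connectomic",
                                         "temporal")) {
  family <- match.arg(family)
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("region table needs a label column and >= 1 value column")
  df <- align_rows(df, parc, path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(vals) <- "double"
  if (ncol(vals) == 1) {
    region_map(vals[, 1], parc, name = colnames(vals)[1])
  } else {
    predictor_table(vals, parc, family = family)
  }
}

#' Write a region map or predictor table
#'
#' @param x a `region_map` or `predictor_table`.
#' @param path output path.
#' @param parc the aligned `parcellation` (provides the label column).
#' @param sep field separator.
#' @export
write_region_table <- function(x, path, parc, sep = "\t") {
  if (inherits(x, "region_map")) {
    df <- data.frame(region = parc$region_labels, value = x$values,
                     check.names = FALSE)
    names(df)[2] <- x$name
  } else if (inherits(x, "predictor_table")) {
    df <- data.frame(region = parc$region_labels, x$matrix,
                     check.names = FALSE)
  } else stop("x must be a region_map or predictor_table")
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dense connectivity matrix
#'
#' Reads a dense delimited matrix, with or without header row / label
#' column. Asymmetry up to 1e-8 is removed by averaging with the transpose;
#' larger asymmetry is an error. When labels are present rows and columns
#' are aligned to the parcellation.
#'
#' @param path path to the delimited matrix.
#' @param parc target `parcellation`.
#' @param kind "structural" (nonnegative) or "functional".
#' @return A `network`.
#' @export
read_matrix <- function(path, parc, kind = c("structural", "functional")) {
  kind <- match.arg(kind)
  sep <- detect_sep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  df <- utils::read.table(path, header = has_header, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  has_labels <- is.character(df[[1]])
  if (has_labels) {
    df <- align_rows(df, parc, path)
    m <- as.matrix(df[, -1, drop = FALSE])
    m <- m[, match(parc$region_labels, colnames(m)), drop = FALSE]
    if (anyNA(m)) stop("matrix column labels do not match the parcellation")
  } else {
    m <- as.matrix(df)
  }
  storage.mode(m) <- "double"
  if (nrow(m) != ncol(m))
    stop(sprintf("matrix in %s is not square (%d x %d)", path,
                 nrow(m), ncol(m)))
  dimnames(m) <- NULL
  network(m, parc, kind = kind)
}

#' Write a dense connectivity matrix
#'
#' Writes the weight matrix with a header row and label column so the file
#' round-trips through [read_matrix()] losslessly to full double precision.
#'
#' @param net a `network`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_matrix <- function(net, path, sep = "\t") {
  stopifnot(inherits(net, "network"))
  df <- data.frame(region = rownames(net$weights), net$weights,
                   check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a parcellation table
#'
#' @param parc a `parcellation`.
#' @param path output path.
#' @param sep field separator.
#' @export
write_parcellation <- function(parc, path, sep = "\t") {
  df <- data.frame(region = parc$region_labels, hemisphere = parc$hemisphere,
                   x = parc$centroid_xyz[, 1], y = parc$centroid_xyz[, 2],
                   z = parc$centroid_xyz[, 3],
                   sx = parc$sphere_xyz[, 1], sy = parc$sphere_xyz[, 2],
                   sz = parc$sphere_xyz[, 3])
  if (!is.null(parc$network_id)) df$network_id <- parc$network_id
  if (!is.null(parc$parcel_size)) df$parcel_size <- parc$parcel_size
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a parcellation table written by [write_parcellation()]
#'
#' @param path input path.
#' @return A `parcellation`.
#' @export
read_parcellation <- function(path) {
  sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  parcellation(df$region, df$hemisphere,
               cbind(df$x, df$y, df$z),
               sphere_xyz = cbind(df$sx, df$sy, df$sz),
               network_id = df$network_id,
               parcel_size = df$parcel_size)
}
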