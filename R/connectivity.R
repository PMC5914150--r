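#' ROI time series for one subject and condition
#'
#' @param values Numeric T x d matrix: T timepoints (rows) by d regions
#'   (columns).  Columns must match the atlas order.
#' @param atlas A [region_atlas()] (or character vector / file path).
#' @param subject_id Subject identifier.
#' @param condition Condition label (one of the two brain states).
#' @return An object of class `"roi_timeseries"`.
#' @details Constant (zero-variance) columns are rejected: a region whose
#'   signal never changes has no defined correlation with anything, and such
#'   columns almost always indicate an extraction error upstream.
#' @export
roi_timeseries <- function(values, atlas, subject_id, condition) {
  atlas <- as_atlas(atlas)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != atlas$d)
    stop("time series has ", ncol(values), " columns but atlas has ",
         atlas$d, " regions")
  if (nrow(values) < 3L)
    stop("need at least 3 timepoints, got ", nrow(values))
  if (anyNA(values) || any(!is.finite(values)))
    stop("time series contains non-finite values")
  sds <- apply(values, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ",
         paste(atlas$names[sds == 0], collapse = ", "))
  colnames(values) <- atlas$names
  structure(list(values = values, atlas = atlas,
                 subject_id = as.character(subject_id),
                 condition = as.character(condition),
                 T = nrow(values)),
            class = "roi_timeseries")
}

#' Read an ROI time-series file
#'
#' Delimited text, T rows x d columns, with a header row of region names that
#' must match the atlas (same names, same order).
#'
#' @param path Path to a TSV/CSV file.
#' @param atlas A [region_atlas()] (or character vector / file path).
#' @param subject_id,condition Identifiers attached to the series.
#' @param sep Field separator; `""` (default) auto-detects tab vs comma.
#' @return An [roi_timeseries()].
#' @export
read_roi_timeseries <- function(path, atlas, subject_id, condition, sep = "") {
  atlas <- as_atlas(atlas)
  if (!file.exists(path)) stop("time-series file not found: ", path)
  if (identical(sep, "")) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, comment.char = "")
  if (!identical(colnames(df), atlas$names))
    stop("region header of ", path, " does not match the atlas; first ",
         "mismatch at column ",
         which.max(colnames(df) != atlas$names[seq_len(ncol(df))]))
  roi_timeseries(as.matrix(df), atlas, subject_id, condition)
}

#' Fisher-z functional connectivity from ROI time series
#'
#' Pearson correlation between every pair of regional time courses, mapped to
#' Fisher z scores (`atanh`).  Correlations are clamped to `(-clip, clip)`
#' before the transform so that duplicated or perfectly anti-correlated
#' signals yield large finite z rather than +/-Inf.
#'
#' @param ts An [roi_timeseries()].
#' @param clip Clamp bound for |r|, in (0, 1).  Default `1 - 1e-7`.
#' @return An object of class `"connectivity_matrix"`: list with the d x d
#'   symmetric matrix `z` (zero diagonal), the atlas, `subject_id` and
#'   `condition`.
#' @examples
#' atl <- region_atlas(c("A", "B", "C"))
#' ts <- roi_timeseries(matrix(rnorm(30), 10, 3), atl, "s1", "low")
#' cm <- fisher_connectivity(ts)
#' range(cm$z)
#' @export
fisher_connectivity <- function(ts, clip = 1 - 1e-7) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (!(clip > 0 && clip < 1)) stop("'clip' must lie in (0, 1)")
  r <- stats::cor(ts$values)
  r <- pmin(pmax(r, -clip), clip)
  z <- atanh(r)
  diag(z) <- 0
  z <- (z + t(z)) / 2  # remove any floating asymmetry from cor()
  connectivity_matrix(z, ts$atlas, ts$subject_id, ts$condition)
}

#' Construct a connectivity matrix object
#'
#' @param z Numeric d x d symmetric matrix of Fisher-z correlations; the
#'   diagonal is forced to zero (self-connections are excluded).
#' @param atlas A [region_atlas()] (or character vector / file path).
#' @param subject_id,condition Identifiers.
#' @param tol Symmetry tolerance for validation.
#' @return An object of class `"connectivity_matrix"`.
#' @export
connectivity_matrix <- function(z, atlas, subject_id, condition, tol = 1e-8) {
  atlas <- as_atlas(atlas)
  z <- as.matrix(z)
  storage.mode(z) <- "double"
  if (nrow(z) != atlas$d || ncol(z) != atlas$d)
    stop("matrix is ", nrow(z), "x", ncol(z), " but atlas has ",
         atlas$d, " regions")
  if (any(!is.finite(z))) stop("connectivity matrix has non-finite entries")
  if (max(abs(z - t(z))) > tol) stop("connectivity matrix is not symmetric")
  z <- (z + t(z)) / 2
  diag(z) <- 0
  dimnames(z) <- list(atlas$names, atlas$names)
  structure(list(z = z, atlas = atlas,
                 subject_id = as.character(subject_id),
                 condition = as.character(condition)),
            class = "connectivity_matrix")
}

#' Read a precomputed connectivity matrix from delimited text
#'
#' d x d numeric matrix, optional header row/column of region names (checked
#' against the atlas when present).
#'
#' @inheritParams read_roi_timeseries
#' @return A [connectivity_matrix()].
#' @export
read_connectivity <- function(path, atlas, subject_id, condition, sep = "") {
  atlas <- as_atlas(atlas)
  if (!file.exists(path)) stop("connectivity file not found: ", path)
  if (identical(sep, "")) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- utils::read.table(path, header = FALSE, sep = sep,
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  # header row present if the first row is non-numeric
  if (all(is.na(suppressWarnings(as.numeric(unlist(raw[1L, ])))))) {
    hdr <- as.character(unlist(raw[1L, ]))
    raw <- raw[-1L, , drop = FALSE]
    if (ncol(raw) == atlas$d + 1L) {  # leading row-name column
      raw <- raw[, -1L, drop = FALSE]
      hdr <- hdr[-1L]
    }
    if (!identical(unname(hdr), atlas$names))
      stop("region header of ", path, " does not match the atlas")
  }
  m <- apply(as.matrix(raw), c(1L, 2L), as.numeric)
  if (nrow(m) != atlas$d || ncol(m) != atlas$d)
    stop("matrix in ", path, " is ", nrow(m), "x", ncol(m),
         " but atlas has ", atlas$d, " regions")
  connectivity_matrix(m, atlas, subject_id, condition, tol = 1e-6)
}

#' Write a connectivity matrix as tab-delimited text
#'
#' @param cm A [connectivity_matrix()].
#' @param path Output path.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  utils::write.table(format(cm$z, digits = 10, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = cm$atlas$names)
  invisible(path)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("Fisher-z connectivity matrix: subject ", x$subject_id,
      ", condition ", x$condition, ", ", x$atlas$d, " regions\n", sep = "")
  off <- x$z[upper.tri(x$z)]
  cat(sprintf("  z range [%.3f, %.3f], %.1f%% positive\n",
              min(off), max(off), 100 * mean(off > 0)))
  invisible(x)
}

#' Positive-edge binary adjacency
#'
#' Binarizes a connectivity matrix keeping only positive connections: an edge
#' links regions i and j iff `z[i, j] > tau`.  Negative correlations are
#' dropped, never absolute-valued, and the diagonal is always zero.
#'
#' @param cm A [connectivity_matrix()].
#' @param tau Non-negative threshold on the Fisher-z scale.  The default 0
#'   keeps every positive connection.
#' @return An object of class `"adjacency"`: list with binary matrix `a`,
#'   `tau`, and the atlas.
#' @export
positive_adjacency <- function(cm, tau = 0) {
  stopifnot(inherits(cm, "connectivity_matrix"))
  if (length(tau) != 1L || !is.finite(tau) || tau < 0)
    stop("'tau' must be a single non-negative number (negative thresholds ",
         "would admit negative connections)")
  a <- (cm$z > tau) * 1
  diag(a) <- 0
  a <- a * t(a)  # symmetric by construction, but keep exact
  dimnames(a) <- dimnames(cm$z)
  structure(list(a = a, tau = tau, atlas = cm$atlas,
                 subject_id = cm$subject_id, condition = cm$condition),
            class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  d <- x$atlas$d
  ne <- sum(x$a) / 2
  cat(sprintf("Binary adjacency: %d nodes, %d edges (density %.3f), tau = %g\n",
              d, ne, ne / (d * (d - 1) / 2), x$tau))
  invisible(x)
}

#' Group-averaged connectivity matrix
#'
#' Elementwise mean of the Fisher-z matrices of several subjects measured in
#' the same condition, as used for group-level modularity analysis.
#'
#' @param cms List of [connectivity_matrix()] objects sharing atlas and
#'   condition.
#' @return A [connectivity_matrix()] with `subject_id = "group"`.
#' @export
group_average <- function(cms) {
  if (length(cms) == 0L) stop("empty list of connectivity matrices")
  stopifnot(all(vapply(cms, inherits, logical(1), "connectivity_matrix")))
  d0 <- cms[[1L]]$atlas$d
  cond <- unique(vapply(cms, `[[`, character(1), "condition"))
  if (length(cond) != 1L)
    stop("mixed conditions in group average: ", paste(cond, collapse = ", "))
  if (!all(vapply(cms, function(c) c$atlas$d, integer(1)) == d0))
    stop("connectivity matrices have mismatched dimensions")
  zbar <- Reduce(`+`, lapply(cms, `[[`, "z")) / length(cms)
  connectivity_matrix(zbar, cms[[1L]]$atlas, "group", cond)
}
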