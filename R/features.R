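#' Feature table: subjects x regions values of one graph metric
#'
#' The SVM design matrix.  Each subject contributes exactly one row per
#' condition; columns are regions; values are one nodal graph metric.
#'
#' @param X Numeric n x d matrix (n = subjects x 2 conditions).
#' @param conditions Character/factor of length n with exactly two levels.
#' @param subjects Character vector of length n of subject identifiers.
#' @param metric_name Name of the metric stored (free text).
#' @param atlas Optional [region_atlas()]; defaults to the column names of
#'   `X`, or `R1..Rd` when absent.
#' @return An object of class `"feature_table"`.
#' @export
feature_table <- function(X, conditions, subjects, metric_name = "feature",
                          atlas = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  conditions <- as.character(conditions)
  subjects <- as.character(subjects)
  if (length(conditions) != n || length(subjects) != n)
    stop("'conditions' and 'subjects' must have one entry per row of X")
  lev <- sort(unique(conditions))
  if (length(lev) != 2L)
    stop("need exactly two condition labels, got: ",
         paste(lev, collapse = ", "))
  tab <- table(subjects, conditions)
  bad <- rownames(tab)[apply(tab != 1L, 1L, any)]
  if (length(bad))
    stop("each subject needs exactly one sample per condition; offending ",
         "subject(s): ", paste(bad, collapse = ", "))
  if (is.null(atlas)) {
    nm <- colnames(X)
    atlas <- if (is.null(nm)) region_atlas(paste0("R", seq_len(ncol(X))))
             else region_atlas(nm)
  } else atlas <- as_atlas(atlas)
  if (atlas$d != ncol(X))
    stop("X has ", ncol(X), " columns but atlas has ", atlas$d, " regions")
  colnames(X) <- atlas$names
  rownames(X) <- paste(subjects, conditions, sep = ".")
  structure(list(X = X, conditions = conditions, subjects = subjects,
                 levels = lev, metric = metric_name, atlas = atlas),
            class = "feature_table")
}

#' Compute a feature table from subject-level connectivity matrices
#'
#' Thresholds each matrix to its positive-edge binary graph and computes the
#' requested nodal metric, one row per subject x condition.
#'
#' @param cms List of [connectivity_matrix()] objects covering both
#'   conditions for every subject.
#' @param metric One of `"degree"`, `"clustering"`, `"betweenness"`.
#' @param tau Positive-edge threshold (z units), default 0.
#' @param normalized Normalize betweenness?  Default `FALSE`.
#' @return A [feature_table()].
#' @export
compute_features <- function(cms,
                             metric = c("degree", "clustering", "betweenness"),
                             tau = 0, normalized = FALSE) {
  metric <- match.arg(metric)
  stopifnot(length(cms) > 0,
            all(vapply(cms, inherits, logical(1), "connectivity_matrix")))
  subjects <- vapply(cms, `[[`, character(1), "subject_id")
  conditions <- vapply(cms, `[[`, character(1), "condition")
  rows <- lapply(cms, function(cm)
    nodal_metric(positive_adjacency(cm, tau), metric, normalized = normalized))
  X <- do.call(rbind, rows)
  feature_table(X, conditions, subjects, metric_name = metric,
                atlas = cms[[1L]]$atlas)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table (%s): %d subjects x 2 conditions, %d regions\n",
              x$metric, length(unique(x$subjects)), x$atlas$d))
  invisible(x)
}

#' Write / read a feature table as tab-delimited text
#'
#' Columns: `metric`, `subject`, `condition`, then one column per region.
#'
#' @param ft A [feature_table()].
#' @param path File path.
#' @return `read_feature_table` returns a [feature_table()].
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(metric = ft$metric, subject = ft$subjects,
                   condition = ft$conditions, check.names = FALSE)
  df <- cbind(df, as.data.frame(ft$X, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature-table file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, comment.char = "")
  need <- c("metric", "subject", "condition")
  if (!all(need %in% colnames(df)))
    stop("feature-table file must have columns ", paste(need, collapse = ", "))
  X <- as.matrix(df[, setdiff(colnames(df), need), drop = FALSE])
  feature_table(X, df$condition, df$subject,
                metric_name = as.character(df$metric[1L]))
}
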