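#' Regions with significantly increased metric values
#'
#' One-sided paired t-test per region: is the metric larger in the
#' high-state condition than in the low-state condition across subjects?
#' This is the conventional "manual" way of choosing regions of interest
#' before classification.
#'
#' @param ft A [feature_table()].
#' @param alpha Significance level (uncorrected), default 0.05.
#' @param greater Which condition label is expected to be larger; default
#'   the second (alphabetically later) level.
#' @return A list with `mask` (named 0/1 vector), `p_values` (per region)
#'   and `statistic` (paired t per region).
#' @export
significant_regions <- function(ft, alpha = 0.05, greater = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  if (is.null(greater)) greater <- ft$levels[2L]
  if (!greater %in% ft$levels)
    stop("'greater' must be one of: ", paste(ft$levels, collapse = ", "))
  lower <- setdiff(ft$levels, greater)
  ord <- order(ft$subjects)
  hi <- ft$X[ord, , drop = FALSE][ft$conditions[ord] == greater, , drop = FALSE]
  lo <- ft$X[ord, , drop = FALSE][ft$conditions[ord] == lower, , drop = FALSE]
  diffs <- hi - lo  # rows aligned by subject after ordering
  n <- nrow(diffs)
  mn <- colMeans(diffs)
  sdv <- apply(diffs, 2L, stats::sd)
  tt <- ifelse(sdv == 0, ifelse(mn > 0, Inf, ifelse(mn < 0, -Inf, 0)),
               mn / (sdv / sqrt(n)))
  p <- stats::pt(tt, df = n - 1, lower.tail = FALSE)
  mask <- as.integer(p < alpha)
  names(mask) <- names(p) <- names(tt) <- ft$atlas$names
  list(mask = mask, p_values = p, statistic = tt)
}

#' Manual (significance-based) region selection baseline
#'
#' Selects the regions whose metric increased significantly from the
#' low-load to the high-load condition (one-sided paired t-test,
#' `p < alpha`, uncorrected), then reports the grid-searched LOSOCV SVM
#' accuracy of that fixed region set.
#'
#' @inheritParams significant_regions
#' @param grid Reporting [hyper_grid()].
#' @return An object of class `"manual_select"` with the same core fields as
#'   [ga_select()]: `mask`, `regions`, `cv` (`NULL` with a warning when no
#'   region is significant; the accuracy is then reported as 0),
#'   `p_values`, `alpha`.
#' @export
manual_select <- function(ft, alpha = 0.05, grid = hyper_grid(),
                          greater = NULL) {
  sig <- significant_regions(ft, alpha, greater)
  cv <- NULL
  if (any(sig$mask == 1L)) {
    cv <- svm_grid_search(ft, sig$mask, grid)
  } else {
    warning("no region significant at alpha = ", alpha,
            "; empty selection, accuracy reported as 0")
  }
  structure(list(mask = sig$mask,
                 regions = ft$atlas$names[sig$mask == 1L],
                 accuracy = if (is.null(cv)) 0 else cv$accuracy,
                 cv = cv, p_values = sig$p_values, statistic = sig$statistic,
                 alpha = alpha, metric = ft$metric, train = ft),
            class = "manual_select")
}

#' @export
print.manual_select <- function(x, ...) {
  cat(sprintf("Manual (paired t-test) region selection (%s metric)\n",
              x$metric))
  cat(sprintf("  %d / %d regions significant at alpha = %g\n",
              sum(x$mask), length(x$mask), x$alpha))
  if (!is.null(x$cv))
    cat(sprintf("  full-grid LOSOCV accuracy: %.4f (cost = %g, gamma = %g)\n",
                x$cv$accuracy, x$cv$cost, x$cv$gamma))
  else cat("  empty selection: accuracy 0\n")
  invisible(x)
}

#' @export
coef.manual_select <- function(object, ...) object$mask

#' @export
summary.manual_select <- function(object, ...) {
  print(object)
  if (length(object$regions)) {
    cat("  selected regions:\n")
    cat(paste0("    ", object$regions, collapse = "\n"), "\n")
  }
  invisible(object)
}
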