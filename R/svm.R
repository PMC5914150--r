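#' Hyperparameter grid for the RBF C-SVM
#'
#' @param cost Strictly increasing vector of positive soft-margin penalties.
#' @param gamma Strictly increasing vector of positive RBF widths.
#' @return An object of class `"hyper_grid"`.
#' @details The default grid is the conventional powers-of-two search,
#'   `C = 2^(-5), 2^(-3), ..., 2^15` crossed with
#'   `gamma = 2^(-15), 2^(-13), ..., 2^3`.
#' @export
hyper_grid <- function(cost = 2^seq(-5, 15, by = 2),
                       gamma = 2^seq(-15, 3, by = 2)) {
  cost <- as.numeric(cost); gamma <- as.numeric(gamma)
  if (!length(cost) || !length(gamma))
    stop("grid must have at least one cost and one gamma")
  if (any(cost <= 0) || any(gamma <= 0))
    stop("cost and gamma must be positive")
  if (is.unsorted(cost, strictly = TRUE) || is.unsorted(gamma, strictly = TRUE))
    stop("cost and gamma must be strictly increasing")
  structure(list(cost = cost, gamma = gamma), class = "hyper_grid")
}

#' @rdname hyper_grid
#' @details `coarse_hyper_grid()` is a small 3 x 3 subgrid used by default
#'   inside the genetic-algorithm fitness evaluation, where a full grid per
#'   candidate mask would dominate runtime.
#' @export
coarse_hyper_grid <- function() hyper_grid(cost = 2^c(-1, 3, 7),
                                           gamma = 2^c(-9, -5, -1))

#' @export
print.hyper_grid <- function(x, ...) {
  cat("Hyperparameter grid:", length(x$cost), "x", length(x$gamma),
      "(cost x gamma)\n")
  invisible(x)
}

# --- RBF C-SVM fit/predict backbone -------------------------------------
#
# LOSOCV x grid search x GA fitness evaluates tens of thousands of small
# SVMs, so per-fit overhead matters.  Training always uses the LIBSVM
# engine shipped in e1071; by default we call its registered native trainer
# directly (skipping the formula/data.frame bookkeeping of svm()), after a
# one-time self-check that the direct path reproduces e1071::svm() exactly
# on a probe problem.  If the probe fails (e.g. a future e1071 changes its
# internal interface) every fit silently goes through e1071::svm().
# Decision values for prediction are computed from the support vectors;
# their equality with predict.svm is asserted in the test suite.

.svm_backend <- new.env(parent = emptyenv())

svm_native_symbol <- function() {
  if (is.null(.svm_backend$checked)) {
    sym <- tryCatch(get("R_svmtrain", envir = asNamespace("e1071")),
                    error = function(e) NULL)
    ok <- FALSE
    if (!is.null(sym)) {
      ok <- tryCatch({
        # deterministic probe data; must not touch the session RNG stream
        X <- matrix(sin(seq_len(80) * 1.7) + cos(seq_len(80)^2), 20, 4)
        y <- factor(rep(c("a", "b"), 10))
        f <- svmtrain_direct(sym, X, y, cost = 2, gamma = 0.3)
        m <- e1071::svm(x = X, y = y, scale = FALSE, kernel = "radial",
                        cost = 2, gamma = 0.3, fitted = FALSE)
        isTRUE(all.equal(f$rho, m$rho)) &&
          identical(f$index, m$index) &&
          isTRUE(all.equal(f$coefs, as.numeric(m$coefs))) &&
          identical(f$labels, m$labels)
      }, error = function(e) FALSE)
    }
    .svm_backend$sym <- if (ok) sym else NULL
    .svm_backend$checked <- TRUE
  }
  .svm_backend$sym
}

# minimal marshalling for binary C-classification with RBF kernel,
# mirroring e1071::svm.default's .C(R_svmtrain, ...) call
svmtrain_direct <- function(sym, X, y, cost, gamma) {
  nr <- nrow(X)
  cret <- .C(sym,
             as.double(t(X)), as.integer(nr), as.integer(ncol(X)),
             as.double(as.integer(y)),
             as.integer(0), as.integer(0),          # no sparse index
             as.integer(0),                          # type: C-classification
             as.integer(2),                          # kernel: radial
             as.integer(3), as.double(gamma), as.double(0),
             as.double(cost), as.double(0.5),
             as.integer(0), as.double(0), as.integer(0),  # class weights
             as.double(40), as.double(0.001), as.double(0.1),
             as.integer(1),                          # shrinking
             as.integer(0), as.integer(0), as.integer(0),
             nclasses = integer(1), nr = integer(1), index = integer(nr),
             labels = integer(2), nSV = integer(2), rho = double(1),
             coefs = double(nr), sigma = double(1), probA = double(1),
             probB = double(1), cresults = double(0), ctotal1 = double(1),
             ctotal2 = double(1),
             error = paste(rep(" ", 255), collapse = ""))
  if (!identical(cret$error, paste(rep(" ", 255), collapse = "")) &&
      nzchar(trimws(cret$error)))
    stop("LIBSVM: ", trimws(cret$error))
  idx <- cret$index[seq_len(cret$nr)]
  list(SV = X[idx, , drop = FALSE], coefs = cret$coefs[seq_len(cret$nr)],
       rho = cret$rho, labels = cret$labels[1:2], index = idx,
       levels = levels(y))
}

# Train via whichever backend is available; unified return shape.
svm_train <- function(Xtr, ytr, cost, gamma) {
  sym <- svm_native_symbol()
  if (!is.null(sym)) return(svmtrain_direct(sym, Xtr, ytr, cost, gamma))
  m <- e1071::svm(x = Xtr, y = ytr, scale = FALSE, kernel = "radial",
                  cost = cost, gamma = gamma, fitted = FALSE)
  list(SV = m$SV, coefs = as.numeric(m$coefs), rho = m$rho,
       labels = m$labels, index = m$index, levels = m$levels)
}

# Predict labels from a fit given squared distances of the test rows to
# *all* training rows (columns indexed by the fit's SV indices).
svm_decide <- function(fit, gamma, d2_all) {
  f <- exp(-gamma * d2_all[, fit$index, drop = FALSE]) %*% fit$coefs -
    fit$rho
  fit$levels[fit$labels[ifelse(f > 0, 1L, 2L)]]
}

# Fit a binary RBF C-SVM on (Xtr, ytr) and predict labels for Xte.
svm_fit_predict <- function(Xtr, ytr, Xte, cost, gamma) {
  d2 <- pmax(outer(rowSums(Xte^2), rowSums(Xtr^2), "+") -
               2 * (Xte %*% t(Xtr)), 0)
  svm_decide(svm_train(Xtr, ytr, cost, gamma), gamma, d2)
}

# One-time fold preparation for LOSOCV: per held-out subject, the
# standardized training matrix (mask applied; mean/SD from the training
# fold only), the training labels, the held-out row indices, and the
# squared distances of the standardized held-out rows to every training
# row.  Shared across all (cost, gamma) evaluations for the same mask.
prepare_folds <- function(ft, mask) {
  subj <- unique(ft$subjects)
  X <- ft$X[, mask, drop = FALSE]
  y <- factor(ft$conditions, levels = ft$levels)
  lapply(subj, function(s) {
    te <- ft$subjects == s
    Xtr <- X[!te, , drop = FALSE]
    ytr <- y[!te]
    if (length(unique(ytr)) < 2L)
      stop("training fold for held-out subject ", s,
           " contains a single class")
    mu <- colMeans(Xtr)
    s2 <- sqrt(colMeans(Xtr^2) - mu^2) * sqrt(nrow(Xtr) / (nrow(Xtr) - 1))
    s2[s2 < 1e-12] <- 1
    Xtr <- sweep(sweep(Xtr, 2L, mu), 2L, s2, "/")
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2L, mu), 2L, s2, "/")
    d2 <- pmax(outer(rowSums(Xte^2), rowSums(Xtr^2), "+") -
                 2 * (Xte %*% t(Xtr)), 0)
    list(held_out = s, te = which(te), Xtr = Xtr, ytr = ytr, d2 = d2,
         train_subjects = unique(ft$subjects[!te]))
  })
}

# Pooled LOSOCV predictions at one (cost, gamma) over prepared folds.
losocv_core <- function(folds, n, cost, gamma) {
  pred <- character(n)
  for (f in folds) {
    fit <- svm_train(f$Xtr, f$ytr, cost, gamma)
    pred[f$te] <- svm_decide(fit, gamma, f$d2)
  }
  pred
}

# reference path used by the test suite to validate svm_fit_predict
svm_fit_predict_reference <- function(Xtr, ytr, Xte, cost, gamma) {
  m <- e1071::svm(x = Xtr, y = ytr, scale = FALSE, kernel = "radial",
                  cost = cost, gamma = gamma)
  as.character(stats::predict(m, Xte))
}

#' Leave-one-subject-out cross-validated SVM accuracy
#'
#' For each subject in turn, trains an RBF C-SVM on every other subject's
#' samples (both conditions) and predicts the held-out subject's two samples;
#' accuracy is pooled over all held-out samples.  Features are restricted to
#' `mask` and z-score standardized with means/SDs estimated on the training
#' fold only, so no information from the held-out subject enters training.
#'
#' @param ft A [feature_table()].
#' @param mask Logical or 0/1 vector of length d selecting features; `NULL`
#'   selects all.
#' @param cost,gamma SVM hyperparameters (positive).
#' @param details Keep per-fold training-subject membership (for auditing
#'   that no held-out subject leaks into training)?
#' @return An object of class `"svm_cv"`: `accuracy`, `predictions` (named
#'   by sample), `truth`, `cost`, `gamma`, and optionally `folds`.
#' @export
losocv_svm <- function(ft, mask = NULL, cost = 1, gamma = NULL,
                       details = FALSE) {
  stopifnot(inherits(ft, "feature_table"))
  d <- ncol(ft$X)
  mask <- check_mask(mask, d)
  if (!any(mask)) stop("degenerate mask: no features selected")
  if (is.null(gamma)) gamma <- 1 / sum(mask)
  if (cost <= 0 || gamma <= 0) stop("cost and gamma must be positive")
  if (length(unique(ft$subjects)) < 3L)
    stop("need at least 3 subjects for LOSOCV")
  folds <- prepare_folds(ft, mask)
  pred <- losocv_core(folds, nrow(ft$X), cost, gamma)
  names(pred) <- rownames(ft$X)
  folds <- if (details)
    lapply(folds, `[`, c("held_out", "train_subjects", "te")) else NULL
  structure(list(accuracy = mean(pred == ft$conditions),
                 predictions = pred, truth = ft$conditions,
                 subjects = ft$subjects,
                 cost = cost, gamma = gamma, folds = folds),
            class = "svm_cv")
}

#' @export
print.svm_cv <- function(x, ...) {
  cat(sprintf("LOSOCV RBF C-SVM: accuracy %.4f (cost = %g, gamma = %g)\n",
              x$accuracy, x$cost, x$gamma))
  invisible(x)
}

#' Grid-searched LOSOCV accuracy
#'
#' Evaluates [losocv_svm()] at every (cost, gamma) pair of the grid and
#' returns the result at the maximizing pair.  Ties are broken in favour of
#' the smallest cost, then the smallest gamma.
#'
#' @inheritParams losocv_svm
#' @param grid A [hyper_grid()].
#' @return An `"svm_cv"` object with an extra element `grid_accuracy`
#'   (matrix of accuracies, rows = cost, cols = gamma).
#' @export
svm_grid_search <- function(ft, mask = NULL, grid = hyper_grid()) {
  stopifnot(inherits(ft, "feature_table"), inherits(grid, "hyper_grid"))
  mask <- check_mask(mask, ncol(ft$X))
  if (!any(mask)) stop("degenerate mask: no features selected")
  if (length(unique(ft$subjects)) < 3L)
    stop("need at least 3 subjects for LOSOCV")
  folds <- prepare_folds(ft, mask)
  n <- nrow(ft$X)
  acc <- matrix(NA_real_, length(grid$cost), length(grid$gamma),
                dimnames = list(cost = format(grid$cost, trim = TRUE),
                                gamma = format(grid$gamma, trim = TRUE)))
  best <- NULL
  for (i in seq_along(grid$cost)) for (j in seq_along(grid$gamma)) {
    pred <- losocv_core(folds, n, grid$cost[i], grid$gamma[j])
    a <- mean(pred == ft$conditions)
    acc[i, j] <- a
    if (is.null(best) || a > best$accuracy) {
      names(pred) <- rownames(ft$X)
      best <- structure(list(accuracy = a, predictions = pred,
                             truth = ft$conditions, subjects = ft$subjects,
                             cost = grid$cost[i], gamma = grid$gamma[j],
                             folds = NULL),
                        class = "svm_cv")
    }
  }
  best$grid_accuracy <- acc
  best
}

# normalize a selection mask to logical of length d
check_mask <- function(mask, d) {
  if (is.null(mask)) return(rep(TRUE, d))
  if (is.logical(mask)) {
    if (length(mask) != d) stop("mask length ", length(mask), " != d = ", d)
    return(mask)
  }
  if (is.numeric(mask)) {
    if (length(mask) != d) stop("mask length ", length(mask), " != d = ", d)
    if (!all(mask %in% c(0, 1))) stop("mask entries must be 0 or 1")
    return(mask == 1)
  }
  stop("mask must be logical or 0/1 numeric")
}
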