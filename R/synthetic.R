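#' Configuration for a synthetic two-condition cohort
#'
#' Describes a within-subject, two-condition cohort (conditions `"A"` = low
#' state, `"B"` = high state) in which a planted subset of regions carries
#' the condition difference.  Two generation modes are supported:
#'
#' * `"network"` — a base inter-regional correlation matrix is drawn from a
#'   low-rank factor model (`n_factors` latent factors plus a common factor
#'   calibrated so the expected positive-edge density matches
#'   `base_density`).  In condition B, `effect` is added to every
#'   correlation incident to a planted region, the matrix is repaired to the
#'   nearest valid correlation matrix (eigenvalue clipping), and per-subject
#'   loading jitter of scale `subject_sd` induces between-subject
#'   variability.  Each subject x condition yields `T` multivariate-normal
#'   timepoints.
#' * `"feature"` — nodal metric tables are emitted directly:
#'   `value = mu_r + b_sr + effect * 1[region planted, condition B] +
#'   N(0, 1) noise`, with `b_sr ~ N(0, subject_sd)` a region-specific
#'   random subject intercept shared by the subject's two conditions (the
#'   exchangeable within-subject correlation assumed by paired tests), so
#'   `effect` is the planted shift in units of the within-subject noise SD.
#'
#' @param d Number of regions (>= 3).  Default 40, a desk-scale stand-in
#'   for a 116-region whole-brain parcellation.
#' @param n_subjects Number of subjects.  Default 28.
#' @param T_len Timepoints per subject x condition (network mode).
#'   Default 150.
#' @param planted Planted region indices, or a single count (the first so
#'   many regions).  Default 10.
#' @param effect Planted effect size; `NULL` picks the mode default
#'   (0.3 correlation units in network mode, 1.5 noise SDs in feature mode).
#' @param subject_sd Between-subject variability scale.  Default 1.0: in
#'   feature mode this puts the between-subject SD of a regional metric at
#'   the within-subject noise SD (ICC 0.5, the mid-range of published
#'   test-retest reliabilities of nodal graph metrics); in network mode it
#'   scales per-subject jitter of the factor loadings.
#' @param base_density Target expected positive-edge density of the base
#'   graph (network mode).  Default 0.6.
#' @param n_factors Latent factors of the base covariance.  Default 5.
#' @param mode `"network"` or `"feature"`.
#' @return An object of class `"synth_config"`.
#' @export
synth_config <- function(d = 40L, n_subjects = 28L, T_len = 150L,
                         planted = 10L, effect = NULL, subject_sd = 1.0,
                         base_density = 0.6, n_factors = 5L,
                         mode = c("network", "feature")) {
  mode <- match.arg(mode)
  d <- as.integer(d); n_subjects <- as.integer(n_subjects)
  stopifnot(d >= 3, n_subjects >= 3, T_len >= 3)
  if (length(planted) == 1L && planted == floor(planted) && planted <= d)
    planted <- seq_len(planted)   # a single number is a count
  planted <- sort(unique(as.integer(planted)))
  if (length(planted) && (min(planted) < 1L || max(planted) > d))
    stop("planted indices must lie in 1..d")
  if (is.null(effect)) effect <- if (mode == "network") 0.3 else 1.5
  if (effect < 0) stop("'effect' must be non-negative")
  stopifnot(subject_sd >= 0, base_density > 0, base_density < 1)
  structure(list(d = d, n_subjects = n_subjects, T_len = as.integer(T_len),
                 planted = planted, effect = effect, subject_sd = subject_sd,
                 base_density = base_density, n_factors = as.integer(n_factors),
                 mode = mode),
            class = "synth_config")
}

# nearest correlation matrix by eigenvalue clipping + unit-diagonal rescale
psd_correlation <- function(r, min_eig = 1e-8) {
  e <- eigen(r, symmetric = TRUE)
  vals <- pmax(e$values, min_eig)
  r2 <- e$vectors %*% (vals * t(e$vectors))
  dsc <- 1 / sqrt(diag(r2))
  r2 <- r2 * tcrossprod(dsc)
  (r2 + t(r2)) / 2
}

# base correlation from k-factor model with a common factor calibrated to
# the target positive-edge density
base_correlation <- function(cfg) {
  L <- matrix(stats::rnorm(cfg$d * cfg$n_factors), cfg$d, cfg$n_factors)
  psi <- stats::runif(cfg$d, 0.5, 1.5)
  frac_pos <- function(cc) {
    s <- tcrossprod(cbind(cc, L)) + diag(psi)
    r <- stats::cov2cor(s)
    mean(r[upper.tri(r)] > 0)
  }
  f0 <- frac_pos(rep(0, cfg$d))
  if (f0 >= cfg$base_density) {
    cc <- rep(0, cfg$d)
  } else {
    up <- 5
    root <- stats::uniroot(function(a) frac_pos(rep(a, cfg$d)) -
                             cfg$base_density,
                           lower = 0, upper = up, extendInt = "upX",
                           tol = 1e-3)
    cc <- rep(root$root, cfg$d)
  }
  list(L = cbind(cc, L), psi = psi)
}

#' Simulate a synthetic two-condition cohort
#'
#' @param cfg A [synth_config()].
#' @param seed Optional integer RNG seed.
#' @return An object of class `"synth_cohort"`: list with `planted` (ground
#'   truth region indices), `atlas`, `config`, and either `series` (network
#'   mode: list of [roi_timeseries()], one per subject x condition) or
#'   `features` (feature mode: a [feature_table()]).
#' @examples
#' coh <- simulate_cohort(synth_config(d = 10, n_subjects = 6, mode = "feature"),
#'                        seed = 1)
#' coh$planted
#' @export
simulate_cohort <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(seed)) set.seed(seed)
  atlas <- region_atlas(sprintf("R%03d", seq_len(cfg$d)))
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  out <- list(planted = cfg$planted, atlas = atlas, config = cfg)

  if (cfg$mode == "feature") {
    mu <- stats::rnorm(cfg$d, 0, 1)          # region baselines
    n <- cfg$n_subjects
    rows <- vector("list", 2L * n)
    subj <- cond <- character(2L * n)
    k <- 0L
    for (s in seq_len(n)) {
      b_s <- stats::rnorm(cfg$d, 0, cfg$subject_sd)  # region-specific
      for (cn in c("A", "B")) {
        k <- k + 1L
        shift <- if (cn == "B") cfg$effect * (seq_len(cfg$d) %in% cfg$planted)
                 else 0
        rows[[k]] <- mu + b_s + shift + stats::rnorm(cfg$d)
        subj[k] <- subjects[s]; cond[k] <- cn
      }
    }
    out$features <- feature_table(do.call(rbind, rows), cond, subj,
                                  metric_name = "synthetic", atlas = atlas)
    class(out) <- "synth_cohort"
    return(out)
  }

  # network mode
  base <- base_correlation(cfg)
  inS <- seq_len(cfg$d) %in% cfg$planted
  bump <- outer(inS, inS, `|`); diag(bump) <- FALSE
  series <- vector("list", 2L * cfg$n_subjects)
  k <- 0L
  for (s in seq_len(cfg$n_subjects)) {
    Ls <- base$L + cfg$subject_sd * matrix(stats::rnorm(length(base$L)),
                                           nrow = cfg$d)
    r_s <- stats::cov2cor(tcrossprod(Ls) + diag(base$psi))
    for (cn in c("A", "B")) {
      r <- r_s
      if (cn == "B" && cfg$effect > 0) {
        r2 <- r + cfg$effect * bump
        sat <- abs(r2[bump]) >= 0.999
        if (mean(sat) > 0.5)
          stop("planted effect saturates most affected correlations at ",
               "+/-1, leaving no room for a valid correlation matrix; ",
               "use a smaller 'effect'")
        r2 <- pmin(pmax(r2, -0.995), 0.995)
        diag(r2) <- 1
        r <- psd_correlation(r2)
      }
      ch <- chol(r + diag(1e-10, cfg$d))
      x <- matrix(stats::rnorm(cfg$T_len * cfg$d), cfg$T_len) %*% ch
      k <- k + 1L
      series[[k]] <- roi_timeseries(x, atlas, subjects[s], cn)
    }
  }
  out$series <- series
  class(out) <- "synth_cohort"
  out
}

#' @export
print.synth_cohort <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Synthetic cohort (%s mode): %d subjects x 2 conditions, %d regions\n",
              cfg$mode, cfg$n_subjects, cfg$d))
  cat(sprintf("  planted regions: %d, effect = %g\n",
              length(x$planted), cfg$effect))
  invisible(x)
}

#' Connectivity matrices of a network-mode cohort
#'
#' @param cohort A network-mode [simulate_cohort()] result.
#' @param clip Passed to [fisher_connectivity()].
#' @return List of [connectivity_matrix()] objects.
#' @export
cohort_connectivity <- function(cohort, clip = 1 - 1e-7) {
  stopifnot(inherits(cohort, "synth_cohort"))
  if (is.null(cohort$series))
    stop("cohort was generated in feature mode; it has no time series")
  lapply(cohort$series, fisher_connectivity, clip = clip)
}

#' Recovery of a planted region set by a selection mask
#'
#' @param mask 0/1 (or logical) selection vector of length d.
#' @param planted Ground-truth planted region indices.
#' @param d Number of regions (defaults to `length(mask)`).
#' @return A list: `jaccard`, `sensitivity`, `specificity`, and
#'   `enrichment_p`, the hypergeometric tail probability of drawing at least
#'   the observed overlap when `sum(mask)` regions are picked at random.
#' @export
recovery_score <- function(mask, planted, d = length(mask)) {
  mask <- check_mask(mask, d)
  sel <- which(mask)
  planted <- sort(unique(as.integer(planted)))
  ov <- length(intersect(sel, planted))
  un <- length(union(sel, planted))
  list(
    jaccard = if (un == 0) 1 else ov / un,
    sensitivity = if (length(planted) == 0) NA_real_ else ov / length(planted),
    specificity = if (d == length(planted)) NA_real_ else
      (d - length(planted) - (length(sel) - ov)) / (d - length(planted)),
    enrichment_p = stats::phyper(ov - 1, length(planted), d - length(planted),
                                 length(sel), lower.tail = FALSE)
  )
}
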