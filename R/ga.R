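#' Genetic algorithm configuration
#'
#' Defaults follow the published parameterization of the wrapper: population
#' 100, 100 generations, two-point crossover at rate 0.7, per-individual
#' mutation probability 0.5 (each gene then flips independently with
#' probability `per_gene_flip_prob`, default 1/d), tournament selection of
#' size 4.
#'
#' @param population_size Number of individuals (>= 2).
#' @param generations Number of generations (>= 1).
#' @param crossover_rate Probability a consecutive pair is recombined.
#' @param mutation_rate Per-individual probability of entering mutation.
#' @param per_gene_flip_prob Per-gene flip probability once an individual
#'   mutates; `NULL` means 1/d, resolved when the chromosome length is known.
#' @param tournament_size Individuals drawn per tournament.
#' @return An object of class `"ga_config"`.
#' @export
ga_config <- function(population_size = 100L, generations = 100L,
                      crossover_rate = 0.7, mutation_rate = 0.5,
                      per_gene_flip_prob = NULL, tournament_size = 4L) {
  stopifnot(population_size >= 2, generations >= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            is.null(per_gene_flip_prob) ||
              (per_gene_flip_prob >= 0 && per_gene_flip_prob <= 1),
            tournament_size >= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 mutation_rate = mutation_rate,
                 per_gene_flip_prob = per_gene_flip_prob,
                 tournament_size = as.integer(tournament_size)),
            class = "ga_config")
}

#' GA operators on binary selection masks
#'
#' `crossover_two_point()` draws two cut points uniformly from `0..d`
#' (sorted; equal cuts allowed) and exchanges the segment strictly between
#' them, so the positionwise multiset of bits across the pair is conserved.
#' `mutate_bitflip()` flips each bit independently with probability `prob`.
#' `select_tournament()` repeatedly draws `k` individuals uniformly with
#' replacement and copies the fittest; ties go to the earliest drawn, which
#' makes selection under all-equal fitness an exactly uniform resample.
#'
#' @param p1,p2 Equal-length 0/1 integer vectors (parents).
#' @param cuts Optional fixed cut points `c(c1, c2)` with
#'   `0 <= c1 <= c2 <= d`; drawn at random when `NULL`.
#' @return `crossover_two_point`: list of two children.
#' @export
crossover_two_point <- function(p1, p2, cuts = NULL) {
  d <- length(p1)
  if (length(p2) != d) stop("parents must have equal length")
  if (is.null(cuts)) cuts <- sort(sample.int(d + 1L, 2L, replace = TRUE) - 1L)
  c1 <- cuts[1L]; c2 <- cuts[2L]
  if (c1 > c2 || c1 < 0 || c2 > d) stop("invalid cut points")
  ch1 <- p1; ch2 <- p2
  if (c2 > c1) {
    seg <- (c1 + 1L):c2
    ch1[seg] <- p2[seg]
    ch2[seg] <- p1[seg]
  }
  list(ch1, ch2)
}

#' @rdname crossover_two_point
#' @param m 0/1 integer vector (chromosome).
#' @param prob Per-gene flip probability in `[0, 1]`.
#' @return `mutate_bitflip`: the mutated chromosome.
#' @export
mutate_bitflip <- function(m, prob) {
  stopifnot(prob >= 0, prob <= 1)
  flip <- stats::runif(length(m)) < prob
  m[flip] <- 1L - m[flip]
  m
}

#' @rdname crossover_two_point
#' @param pop List of chromosomes.
#' @param fitnesses Numeric vector, one fitness per individual.
#' @param k Tournament size.
#' @param count Number of individuals to select.
#' @return `select_tournament`: list of `count` selected chromosomes
#'   (copies).
#' @export
select_tournament <- function(pop, fitnesses, k, count) {
  n <- length(pop)
  if (n == 0L) stop("empty population")
  if (length(fitnesses) != n) stop("one fitness per individual required")
  if (k > n) stop("tournament size exceeds population size")
  out <- vector("list", count)
  for (i in seq_len(count)) {
    idx <- sample.int(n, k, replace = TRUE)
    out[[i]] <- pop[[idx[which.max(fitnesses[idx])]]]  # ties: earliest drawn
  }
  out
}

#' GA fitness: grid-searched LOSOCV accuracy of a mask
#'
#' The objective function of the wrapper: classification accuracy of the
#' masked feature table under leave-one-subject-out cross-validation, with
#' (cost, gamma) grid-searched per mask.  The empty mask is assigned fitness
#' 0 (a classifier with no features is useless, and the GA must be free to
#' generate such individuals without crashing).
#'
#' @param mask 0/1 or logical vector of length d.
#' @param ft A [feature_table()].
#' @param grid A [hyper_grid()] (for GA use, typically [coarse_hyper_grid()]).
#' @return Accuracy fraction in `[0, 1]`.
#' @export
evaluate_fitness <- function(mask, ft, grid = coarse_hyper_grid()) {
  mask <- check_mask(mask, ncol(ft$X))
  if (!any(mask)) return(0)
  svm_grid_search(ft, mask, grid)$accuracy
}

#' Automatic region selection by genetic algorithm
#'
#' Solves `max f(x), x_k in {0,1}` where `f` is the grid-searched LOSOCV
#' accuracy of an RBF C-SVM restricted to the regions selected by `x`.  A
#' generational Holland-style GA is used: i.i.d. Bernoulli(0.5)
#' initialization, tournament selection, two-point crossover on consecutive
#' pairs of the shuffled selected population, per-individual bit-flip
#' mutation, and best-ever ("hall of fame") tracking.  After the final
#' generation the best-ever mask is re-evaluated with the full reporting
#' grid.
#'
#' @param ft A [feature_table()].
#' @param config A [ga_config()].
#' @param fitness_grid [hyper_grid()] used inside fitness evaluation
#'   (default [coarse_hyper_grid()], a small subgrid).
#' @param final_grid [hyper_grid()] used for the final report (default the
#'   full powers-of-two grid).
#' @param seed Integer RNG seed; set for a reproducible run.
#' @param init Optional list of 0/1 vectors seeding the initial population
#'   (e.g. a previously found mask); topped up with random individuals to
#'   `population_size`.
#' @return An object of class `"ga_select"`: `mask` (named 0/1 vector),
#'   `regions` (selected names), `fitness` (best-ever coarse-grid fitness),
#'   `cv` (full-grid `"svm_cv"` for the best mask: accuracy, cost, gamma),
#'   `history` (per-generation best/mean fitness), `config`, `seed`,
#'   `n_evaluations` (unique masks evaluated).
#' @seealso [manual_select()] for the significance-based baseline.
#' @export
ga_select <- function(ft, config = ga_config(),
                      fitness_grid = coarse_hyper_grid(),
                      final_grid = hyper_grid(), seed = NULL, init = NULL) {
  stopifnot(inherits(ft, "feature_table"), inherits(config, "ga_config"))
  if (!is.null(seed)) set.seed(seed)
  d <- ncol(ft$X)
  indpb <- if (is.null(config$per_gene_flip_prob)) 1 / d
           else config$per_gene_flip_prob
  np <- config$population_size

  cache <- new.env(parent = emptyenv())
  fit_one <- function(mask) {
    key <- rawToChar(as.raw(mask + 48L))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    v <- evaluate_fitness(mask, ft, fitness_grid)
    cache[[key]] <- v
    v
  }

  pop <- replicate(np, as.integer(stats::runif(d) < 0.5), simplify = FALSE)
  if (!is.null(init)) {
    init <- lapply(init, function(m) as.integer(check_mask(m, d)))
    pop[seq_along(init)] <- init[seq_len(min(length(init), np))]
  }
  fits <- vapply(pop, fit_one, numeric(1))

  # best-ever ("hall of fame") tracking; at equal fitness the smaller mask
  # wins (parsimony tie-break: of two equally accurate region sets, report
  # the one without the superfluous regions)
  best_mask <- NULL
  best_fit <- -Inf
  update_best <- function(pop, fits) {
    top <- max(fits)
    if (top < best_fit) return(invisible())
    cand <- pop[fits == top]
    sizes <- vapply(cand, sum, numeric(1))
    small <- cand[[which.min(sizes)]]
    if (top > best_fit ||
        (top == best_fit && sum(small) < sum(best_mask))) {
      best_fit <<- top
      best_mask <<- small
    }
    invisible()
  }
  update_best(pop, fits)
  history <- data.frame(generation = 0L, best = best_fit, mean = mean(fits))

  for (gen in seq_len(config$generations)) {
    sel <- select_tournament(pop, fits, config$tournament_size, np)
    sel <- sel[sample.int(np)]  # shuffle before pairing
    for (i in seq(1L, np - 1L, by = 2L)) {
      if (stats::runif(1) < config$crossover_rate) {
        ch <- crossover_two_point(sel[[i]], sel[[i + 1L]])
        sel[[i]] <- ch[[1L]]; sel[[i + 1L]] <- ch[[2L]]
      }
    }
    for (i in seq_len(np)) {
      if (stats::runif(1) < config$mutation_rate)
        sel[[i]] <- mutate_bitflip(sel[[i]], indpb)
    }
    pop <- sel
    fits <- vapply(pop, fit_one, numeric(1))
    update_best(pop, fits)
    history <- rbind(history,
                     data.frame(generation = gen, best = best_fit,
                                mean = mean(fits)))
  }

  final_cv <- if (any(best_mask == 1L))
    svm_grid_search(ft, best_mask, final_grid) else NULL
  names(best_mask) <- ft$atlas$names
  structure(list(mask = best_mask,
                 regions = ft$atlas$names[best_mask == 1L],
                 fitness = best_fit, cv = final_cv, history = history,
                 metric = ft$metric, config = config, seed = seed,
                 n_evaluations = length(ls(cache)), train = ft),
            class = "ga_select")
}

#' @export
print.ga_select <- function(x, ...) {
  cat(sprintf("GA region selection (%s metric)\n", x$metric))
  cat(sprintf("  selected %d / %d regions\n", sum(x$mask), length(x$mask)))
  cat(sprintf("  best fitness (coarse-grid LOSOCV accuracy): %.4f\n",
              x$fitness))
  if (!is.null(x$cv))
    cat(sprintf("  full-grid LOSOCV accuracy: %.4f (cost = %g, gamma = %g)\n",
                x$cv$accuracy, x$cv$cost, x$cv$gamma))
  invisible(x)
}

#' @export
summary.ga_select <- function(object, ...) {
  print(object)
  cat("  generations:", max(object$history$generation),
      " population:", object$config$population_size,
      " unique masks evaluated:", object$n_evaluations, "\n")
  cat("  selected regions:\n")
  cat(paste0("    ", object$regions, collapse = "\n"), "\n")
  invisible(object)
}

#' @export
coef.ga_select <- function(object, ...) object$mask

#' @export
plot.ga_select <- function(x, ...) {
  h <- x$history
  plot(h$generation, h$best, type = "s", ylim = range(c(h$best, h$mean)),
       xlab = "generation", ylab = "LOSOCV accuracy (fitness)",
       main = sprintf("GA fitness trajectory (%s)", x$metric), ...)
  graphics::lines(h$generation, h$mean, lty = 2)
  graphics::legend("bottomright", legend = c("best-ever", "population mean"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Predict conditions for new samples from a fitted selection
#'
#' Re-fits the RBF C-SVM on the full training table, restricted to the
#' selected regions and at the reported (cost, gamma), and predicts the
#' condition of each row of `newdata`.
#'
#' @param object A `"ga_select"` or `"manual_select"` fit.
#' @param newdata A [feature_table()] or numeric matrix with the same d
#'   columns, on the training metric.
#' @param ... Unused.
#' @return Character vector of predicted condition labels.
#' @export
predict.ga_select <- function(object, newdata, ...) {
  if (is.null(object$cv)) stop("empty selection: nothing to predict with")
  ft <- object$train
  if (is.null(ft)) stop("fit does not carry its training table")
  Xnew <- if (inherits(newdata, "feature_table")) newdata$X
          else as.matrix(newdata)
  mask <- object$mask == 1
  X <- ft$X[, mask, drop = FALSE]
  mu <- colMeans(X); s <- apply(X, 2L, stats::sd); s[s < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2L, mu), 2L, s, "/")
  Xn <- sweep(sweep(Xnew[, mask, drop = FALSE], 2L, mu), 2L, s, "/")
  y <- factor(ft$conditions, levels = ft$levels)
  svm_fit_predict(Xs, y, Xn, object$cv$cost, object$cv$gamma)
}

#' @export
predict.manual_select <- predict.ga_select
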