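test_that("two-point crossover exchanges the segment between the cuts", {
  p1 <- rep(0L, 6); p2 <- rep(1L, 6)
  ch <- crossover_two_point(p1, p2, cuts = c(2, 4))
  expect_identical(ch[[1]], c(0L, 0L, 1L, 1L, 0L, 0L))
  expect_identical(ch[[2]], c(1L, 1L, 0L, 0L, 1L, 1L))
  # identical parents -> identical children
  ch2 <- crossover_two_point(p2, p2)
  expect_identical(ch2[[1]], p2)
  expect_identical(ch2[[2]], p2)
  # equal cut points -> children equal parents
  ch3 <- crossover_two_point(p1, p2, cuts = c(3, 3))
  expect_identical(ch3[[1]], p1)
  expect_identical(ch3[[2]], p2)
  expect_error(crossover_two_point(p1, rep(0L, 5)), "equal length")
})

test_that("crossover conserves the positionwise bit multiset across the pair", {
  set.seed(50)
  for (i in 1:100) {
    d <- sample(4:30, 1)
    p1 <- as.integer(runif(d) < 0.5); p2 <- as.integer(runif(d) < 0.5)
    ch <- crossover_two_point(p1, p2)
    expect_identical(ch[[1]] + ch[[2]], p1 + p2)
  }
})

test_that("bit-flip mutation flips each gene independently", {
  set.seed(51)
  m <- as.integer(runif(30) < 0.5)
  expect_identical(mutate_bitflip(m, 0), m)
  expect_identical(mutate_bitflip(m, 1), 1L - m)
  # flip count is Binomial(d, p): mean over trials within 3 sigma
  d <- 116; p <- 0.1; trials <- 2000
  zero <- rep(0L, d)
  flips <- replicate(trials, sum(mutate_bitflip(zero, p)))
  se <- sqrt(d * p * (1 - p) / trials)
  expect_lt(abs(mean(flips) - d * p), 3 * se)
})

test_that("tournament selection copies the fittest of each draw", {
  # two individuals, k = 2 with replacement: the dominant one wins exactly
  # when it is drawn, with probability 1 - (1/2)^2 = 0.75
  pop <- list(c(0L, 0L), c(1L, 1L))
  set.seed(52)
  sel <- select_tournament(pop, c(0, 1), k = 2, count = 4000)
  frac_best <- mean(vapply(sel, identical, logical(1), pop[[2]]))
  expect_lt(abs(frac_best - 0.75), 3 * sqrt(0.75 * 0.25 / 4000))
  # equal fitness: ties go to the earliest drawn, so selection is a
  # uniform resample
  set.seed(53)
  sel2 <- select_tournament(pop, c(1, 1), k = 2, count = 4000)
  frac_first <- mean(vapply(sel2, identical, logical(1), pop[[1]]))
  expect_lt(abs(frac_first - 0.5), 3 * sqrt(0.25 / 4000))
  # determinism under a fixed seed
  set.seed(99); s1 <- select_tournament(pop, c(0.3, 0.6), 2, 10)
  set.seed(99); s2 <- select_tournament(pop, c(0.3, 0.6), 2, 10)
  expect_identical(s1, s2)
  expect_error(select_tournament(list(), numeric(0), 2, 1), "empty")
  expect_error(select_tournament(pop, c(0, 1), k = 7, count = 1), "exceeds")
})

test_that("fitness is grid-searched LOSOCV accuracy with empty mask pinned to 0", {
  set.seed(53)
  coh <- tiny_planted(1, d = 6, n_subjects = 6, planted = 2)
  ft <- coh$features
  expect_identical(evaluate_fitness(rep(0, 6), ft), 0)
  g <- fast_grid()
  expect_equal(evaluate_fitness(rep(1, 6), ft, g),
               svm_grid_search(ft, rep(1, 6), g)$accuracy)
})

test_that("informative masks outscore random masks of equal size on planted data", {
  coh <- tiny_planted(7, d = 12, n_subjects = 10, planted = 4, effect = 2)
  ft <- coh$features
  g <- fast_grid()
  planted_mask <- as.integer(seq_len(12) %in% coh$planted)
  f_planted <- evaluate_fitness(planted_mask, ft, g)
  set.seed(54)
  f_random <- replicate(20, {
    m <- integer(12); m[sample(12, 4)] <- 1L
    evaluate_fitness(m, ft, g)
  })
  expect_gt(f_planted, mean(f_random))
})

test_that("the GA is reproducible, monotone in best-ever fitness, and cannot
           lose a seeded optimum under pure selection", {
  coh <- tiny_planted(3, d = 10, n_subjects = 7, planted = 3, effect = 2.5)
  ft <- coh$features
  cfg <- ga_config(population_size = 8, generations = 4)
  g <- fast_grid()
  r1 <- ga_select(ft, cfg, fitness_grid = g, final_grid = g, seed = 11)
  r2 <- ga_select(ft, cfg, fitness_grid = g, final_grid = g, seed = 11)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$history, r2$history)
  expect_equal(r1$cv$accuracy, r2$cv$accuracy)
  # best-ever trajectory is non-decreasing
  expect_true(all(diff(r1$history$best) >= 0))
  # reported best fitness is reproducible from the reported mask
  expect_equal(r1$fitness, evaluate_fitness(r1$mask, ft, g))
  # selection alone cannot lose an injected optimum
  planted_mask <- as.integer(seq_len(10) %in% coh$planted)
  f_opt <- evaluate_fitness(planted_mask, ft, g)
  r3 <- ga_select(ft, ga_config(population_size = 6, generations = 3,
                                crossover_rate = 0, mutation_rate = 0),
                  fitness_grid = g, final_grid = g, seed = 12,
                  init = list(planted_mask))
  expect_gte(r3$fitness, f_opt)
})

test_that("manual baseline selects planted regions and rejects null tables", {
  # identical condition tables -> nothing selected, accuracy 0 with warning
  set.seed(60)
  Xhalf <- matrix(rnorm(6 * 5), 6, 5)
  ft0 <- feature_table(Xhalf[rep(1:6, each = 2), ],
                       rep(c("A", "B"), 6),
                       rep(sprintf("S%d", 1:6), each = 2), "const")
  expect_warning(m0 <- manual_select(ft0, grid = fast_grid()),
                 "no region significant")
  expect_identical(sum(m0$mask), 0L)
  expect_identical(m0$accuracy, 0)
  # planted cohort: planted regions found, selection beats chance
  coh <- tiny_planted(8, d = 14, n_subjects = 12, planted = 4, effect = 2)
  man <- manual_select(coh$features, grid = fast_grid())
  rec <- recovery_score(coef(man), coh$planted)
  expect_gte(rec$sensitivity, 0.75)
  expect_gt(man$accuracy, 0.6)
  # p-values live in [0,1] and match the one-sided direction
  expect_true(all(man$p_values >= 0 & man$p_values <= 1))
  flipped <- significant_regions(coh$features, greater = "A")
  expect_lte(sum(flipped$mask), 1)   # wrong direction finds ~nothing
})

test_that("manual selection respects its false-positive budget under the null", {
  set.seed(61)
  fp <- replicate(40, {
    coh <- simulate_cohort(synth_config(d = 20, n_subjects = 10, planted = 0,
                                        effect = 0, mode = "feature"))
    sum(significant_regions(coh$features)$mask)
  })
  # mean false positives <= alpha * d (with sampling slack)
  expect_lt(mean(fp), 0.05 * 20 * 1.5)
})
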