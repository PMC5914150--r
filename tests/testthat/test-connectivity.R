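test_that("atlas construction validates names and rejects degenerate input", {
  atl <- region_atlas(c("a", "b", "c", "d"))
  expect_s3_class(atl, "region_atlas")
  expect_identical(atl$d, 4L)
  expect_error(region_atlas(c("a", "b")), "at least 3")
  expect_error(region_atlas(c("a", "b", "a")), "duplicated")
})

test_that("Fisher-z connectivity matches closed-form atanh on known signals", {
  atl <- region_atlas(c("r1", "r2", "r3"))
  # orthogonal square waves: r = 0 -> z = 0
  v1 <- c(1, -1, 1, -1); v2 <- c(1, 1, -1, -1)
  ts <- roi_timeseries(cbind(v1, v2, c(0.5, 1.2, -0.3, 0.8)), atl, "s1", "A")
  cm <- fisher_connectivity(ts)
  expect_equal(cm$z[1, 2], 0)
  # r = 0.5 -> z = atanh(0.5) ~ 0.549306; construct exact-correlation pair
  x <- rnorm(200)
  e <- rnorm(200)
  e <- residuals(lm(e ~ x))                       # orthogonalize
  x <- as.numeric(scale(x)); e <- as.numeric(scale(e))
  y <- 0.5 * x + sqrt(1 - 0.25) * e               # cor(x, y) = 0.5 exactly
  ts2 <- roi_timeseries(cbind(x, y, rnorm(200)), atl, "s1", "A")
  cm2 <- fisher_connectivity(ts2)
  expect_equal(cm2$z[1, 2], atanh(0.5), tolerance = 1e-10)
  expect_equal(cm2$z[1, 2], 0.54931, tolerance = 1e-5)
})

test_that("perfect correlation is clamped to a finite z", {
  atl <- region_atlas(c("r1", "r2", "r3"))
  x <- rnorm(50)
  ts <- roi_timeseries(cbind(x, x, rnorm(50)), atl, "s1", "A")
  cm <- fisher_connectivity(ts)
  expect_true(is.finite(cm$z[1, 2]))
  expect_equal(cm$z[1, 2], atanh(1 - 1e-7))
  cm2 <- fisher_connectivity(ts, clip = 0.99)
  expect_equal(cm2$z[1, 2], atanh(0.99))
  expect_error(fisher_connectivity(ts, clip = 1), "clip")
})

test_that("degenerate time series are rejected with informative errors", {
  atl <- region_atlas(c("r1", "r2", "r3"))
  expect_error(roi_timeseries(cbind(rnorm(10), rep(2, 10), rnorm(10)),
                              atl, "s1", "A"),
               "zero-variance.*r2")
  expect_error(roi_timeseries(matrix(rnorm(6), 2, 3), atl, "s1", "A"),
               "3 timepoints")
})

test_that("connectivity matrices are symmetric with zero diagonal and are
           invariant to increasing affine transforms of the signal", {
  atl <- region_atlas(paste0("r", 1:6))
  set.seed(11)
  for (rep in 1:20) {
    v <- matrix(rnorm(20 * 6), 20, 6)
    cm <- fisher_connectivity(roi_timeseries(v, atl, "s", "A"))
    expect_identical(max(abs(cm$z - t(cm$z))), 0)
    expect_identical(unname(diag(cm$z)), rep(0, 6))
    # affine transform per region: correlations unchanged
    v2 <- sweep(sweep(v, 2, runif(6, 0.5, 3), "*"), 2, rnorm(6), "+")
    cm2 <- fisher_connectivity(roi_timeseries(v2, atl, "s", "A"))
    expect_equal(cm2$z, cm$z, tolerance = 1e-12)
  }
})

test_that("positive adjacency keeps only positive connections above tau", {
  atl <- region_atlas(c("a", "b", "c"))
  z <- matrix(0, 3, 3)
  z[1, 2] <- z[2, 1] <- 0.3
  z[1, 3] <- z[3, 1] <- -0.2
  cm <- connectivity_matrix(z, atl, "s", "A")
  a <- positive_adjacency(cm, 0)
  expect_identical(unname(a$a[1, 2]), 1)
  expect_identical(unname(a$a[1, 3]), 0)   # negative dropped, not |.|
  expect_identical(unname(a$a[2, 3]), 0)   # zero is not > 0
  # all-negative matrix -> empty graph
  zneg <- -abs(matrix(rnorm(9), 3)); zneg <- (zneg + t(zneg)) / 2; diag(zneg) <- 0
  expect_identical(sum(positive_adjacency(connectivity_matrix(zneg, atl, "s", "A"))$a), 0)
  # strict threshold boundary
  z2 <- matrix(0, 3, 3); z2[1, 2] <- z2[2, 1] <- 0.6; z2[1, 3] <- z2[3, 1] <- 0.5
  cm2 <- connectivity_matrix(z2, atl, "s", "A")
  expect_identical(sum(positive_adjacency(cm2, 0.5)$a), 2)  # one edge
  expect_error(positive_adjacency(cm2, -0.1), "non-negative")
})

test_that("positive adjacency is monotone in tau", {
  atl <- region_atlas(paste0("r", 1:8))
  set.seed(21)
  z <- matrix(rnorm(64, sd = 0.5), 8); z <- (z + t(z)) / 2; diag(z) <- 0
  cm <- connectivity_matrix(z, atl, "s", "A")
  taus <- c(0, 0.1, 0.3, 0.6)
  edges <- lapply(taus, function(t) positive_adjacency(cm, t)$a)
  for (i in seq_len(length(taus) - 1))
    expect_true(all(edges[[i + 1]] <= edges[[i]]))
})

test_that("group averaging is an elementwise mean preserving structure", {
  atl <- region_atlas(c("a", "b", "c"))
  z1 <- matrix(0, 3, 3); z1[1, 2] <- z1[2, 1] <- 0.2
  z2 <- matrix(0, 3, 3); z2[1, 2] <- z2[2, 1] <- 0.6
  cm1 <- connectivity_matrix(z1, atl, "s1", "A")
  cm2 <- connectivity_matrix(z2, atl, "s2", "A")
  avg <- group_average(list(cm1, cm2))
  expect_equal(unname(avg$z[1, 2]), 0.4)
  # idempotent on identical matrices
  expect_equal(group_average(list(cm1, cm1, cm1))$z, cm1$z)
  # closure: mean of symmetric matrices is symmetric with zero diagonal
  expect_identical(max(abs(avg$z - t(avg$z))), 0)
  expect_identical(unname(diag(avg$z)), rep(0, 3))
  # errors
  cmB <- connectivity_matrix(z2, atl, "s2", "B")
  expect_error(group_average(list(cm1, cmB)), "mixed conditions")
  expect_error(group_average(list()), "empty")
  atl4 <- region_atlas(c("a", "b", "c", "d"))
  cm4 <- connectivity_matrix(matrix(0, 4, 4), atl4, "s3", "A")
  expect_error(group_average(list(cm1, cm4)), "mismatched")
})

test_that("time-series and matrix readers round-trip and validate the atlas", {
  atl <- region_atlas(c("ra", "rb", "rc"))
  dir <- withr::local_tempdir()
  # time series with header
  v <- matrix(rnorm(30), 10, 3)
  tsf <- file.path(dir, "ts.tsv")
  write.table(setNames(as.data.frame(v), atl$names), tsf, sep = "\t",
              quote = FALSE, row.names = FALSE)
  ts <- read_roi_timeseries(tsf, atl, "s1", "A")
  expect_equal(unname(ts$values), v, tolerance = 1e-6)
  # wrong atlas order rejected
  atl_wrong <- region_atlas(c("rb", "ra", "rc"))
  expect_error(read_roi_timeseries(tsf, atl_wrong, "s1", "A"), "match")
  # connectivity round-trip through the writer
  cm <- fisher_connectivity(ts)
  cmf <- file.path(dir, "cm.tsv")
  write_connectivity(cm, cmf)
  cm2 <- read_connectivity(cmf, atl, "s1", "A")
  expect_equal(cm2$z, cm$z, tolerance = 1e-8)
  # dimension mismatch names the file
  atl4 <- region_atlas(c("ra", "rb", "rc", "rd"))
  expect_error(read_connectivity(cmf, atl4, "s1", "A"), "cm.tsv|match|regions")
})
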