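test_that("partition splits by membership with masks carried along", {
  sim <- simulate_dataset(small_config(seed = 2, missing_rate = 0.1))
  parts <- partition_matrix(sim$matrix, sim$design)
  expect_equal(ncol(parts$group1), 25L)
  expect_equal(ncol(parts$group2), 20L)
  expect_identical(cbind(parts$group1, parts$group2), sim$matrix$values)

  # shuffled design file order leads to the same partition
  ids <- sim$design$sample_ids
  perm <- sample(seq_along(ids))
  path <- write_temp_csv(c("sample_id,group",
                           paste(ids[perm], sim$design$labels[perm], sep = ",")))
  d2 <- read_group_design(path, sample_ids = ids,
                          levels = c("control", "disease"))
  parts2 <- partition_matrix(sim$matrix, d2)
  expect_identical(parts2$index1, parts$index1)

  expect_error(partition_matrix(sim$matrix,
                                group_design(rep(c("a", "b"), c(43, 2)))),
               "at least 3")
})

test_that("IQR rule flags cells beyond the quartile fences only", {
  # quartiles of (1,2,3,4,100) by linear interpolation: Q1 = 2, Q3 = 4,
  # fences -1 and 7
  expect_identical(iqr_outliers(c(1, 2, 3, 4, 100)),
                   c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_false(any(iqr_outliers(rep(5, 6))))
  expect_false(any(iqr_outliers(c(-1, 0, 1))))
  expect_warning(flags <- iqr_outliers(c(1, NA, NA, 2)), "fewer than 3")
  expect_false(any(flags))
  # NA cells are never flagged
  f <- iqr_outliers(c(1, 2, NA, 3, 50))
  expect_false(f[3])
  expect_true(f[5])
})

test_that("reconstruction is the identity on clean observed cells", {
  sim <- simulate_dataset(small_config(seed = 5, missing_rate = 0.15,
                                       outlier_rate = 0.05))
  rec <- suppressWarnings(reconstruct_rsvd(sim$matrix, sim$design))
  untouched <- !rec$replaced_mask
  expect_identical(rec$reconstructed[untouched], sim$matrix$values[untouched])
  expect_false(anyNA(rec$reconstructed))
  expect_true(all(rec$replaced_mask[sim$missing_mask]))

  # clean complete rank-1 per-group matrix passes through exactly
  r1 <- rank1_matrix(p = 8L, n = 10L, lambda = 40)
  design <- group_design(rep(c("g1", "g2"), each = 5))
  rec2 <- reconstruct_rsvd(r1$x, design)
  expect_false(any(rec2$outlier_mask))
  expect_identical(rec2$reconstructed, r1$x)
})

test_that("missing and corrupted cells of a rank-1 group matrix are restored", {
  r1 <- rank1_matrix(p = 6L, n = 10L, lambda = 60)
  x <- r1$x
  design <- group_design(rep(c("g1", "g2"), each = 5))
  truth_12 <- x[1, 2]
  x[1, 2] <- NA                       # missing cell
  x[4, 8] <- x[4, 8] * 50             # corrupted cell
  rec <- reconstruct_rsvd(x, design)
  expect_equal(rec$reconstructed[1, 2], truth_12, tolerance = 1e-4)
  expect_true(rec$outlier_mask[4, 8])
  expect_lt(abs(rec$reconstructed[4, 8] - r1$x[4, 8]) / abs(r1$x[4, 8]), 0.10)
})

test_that("reconstruction beats zero imputation once outliers are present", {
  for (orate in c(0.03, 0.07)) {
    worse <- 0L
    for (rep_i in 1:6) {
      sim <- simulate_dataset(small_config(seed = 100 + rep_i,
                                           missing_rate = 0.10,
                                           outlier_rate = orate))
      rec <- suppressWarnings(reconstruct_rsvd(sim$matrix, sim$design))
      if (rmse(sim$clean, rec$reconstructed) >=
            rmse(sim$clean, impute_zero(sim$matrix))) worse <- worse + 1L
    }
    expect_identical(worse, 0L)
  }
})

test_that("zero imputation replaces exactly the missing cells", {
  sim <- simulate_dataset(small_config(seed = 3, missing_rate = 0.2))
  z <- impute_zero(sim$matrix)
  expect_true(all(z[sim$missing_mask] == 0))
  expect_identical(z[!sim$missing_mask], sim$matrix$values[!sim$missing_mask])
  x <- matrix(1:12 + 0, 3, 4)
  expect_identical(impute_zero(x), x)
})

test_that("kNN imputation averages the nearest rows' values", {
  # duplicate rows: the missing cell copies its twin (k = 1)
  x <- rbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(9, 9, 9, 9))
  x1 <- x
  x1[1, 3] <- NA
  expect_equal(impute_knn(x1, k = 1)[1, 3], 3)

  # target ~ 0-vector; k = 2 neighbours are the 0- and 1-rows -> mean 0.5
  y <- rbind(c(0.01, 0.02, NA, 0.01),
             c(0, 0, 0, 0),
             c(1, 1, 1, 1),
             c(10, 10, 10, 10))
  expect_equal(impute_knn(y, k = 2)[1, 3], 0.5)

  complete <- matrix(rnorm(40), 10, 4)
  expect_identical(impute_knn(complete, k = 3), complete)
  expect_error(impute_knn(complete, k = 10), "k \\+ 1")
  allna <- matrix(c(1, NA, 2, NA, 3, NA), 3, 2, byrow = TRUE)
  expect_error(impute_knn(rbind(allna, allna), k = 1), "every row")
})

test_that("random-forest imputation recovers linear structure deterministically", {
  set.seed(8)
  base <- runif(80, 0, 10)
  base[5] <- 5  # keep the target inside the bulk of the training range
  x <- rbind(base, 2 * base, 3 * base + 1, base + rnorm(80, 0, 0.01),
             2 * base - 1)
  rownames(x) <- NULL
  x[2, 5] <- NA
  truth <- 2 * base[5]
  a <- impute_rf(x, n_trees = 200, seed = 9, mtry = 4)
  b <- impute_rf(x, n_trees = 200, seed = 9, mtry = 4)
  expect_identical(a, b)
  expect_lt(abs(a[2, 5] - truth) / abs(truth), 0.05)
  complete <- matrix(rnorm(50), 10, 5)
  expect_identical(impute_rf(complete), complete)
})
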