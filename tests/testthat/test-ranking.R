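test_that("a perfectly separating feature ranks first", {
  set.seed(31)
  n1 <- 12L; n2 <- 12L
  design <- group_design(rep(c("ctl", "dis"), c(n1, n2)))
  x <- matrix(rnorm(6 * (n1 + n2)), 6, n1 + n2,
              dimnames = list(paste0("f", 1:6), NULL))
  x[1, ] <- c(rnorm(n1, 0, 0.2), rnorm(n2, 5, 0.2))  # separator
  rk <- svm_rank(x, design, seed = 1)
  expect_identical(rk$metabolite_id[rk$rank == 1], "f1")
  expect_true(all(diff(rk$importance_score) <= 0))
  expect_setequal(rk$metabolite_id, rownames(x))

  # refit on the top-1 feature separates the training samples completely
  cv <- crossval_classify(x[rk$metabolite_id[1], , drop = FALSE], design,
                          folds = 4, seed = 2)
  expect_equal(cv$accuracy, 100)
})

test_that("ranking is deterministic and ties break toward lower row index", {
  set.seed(32)
  design <- group_design(rep(c("a", "b"), each = 10))
  x <- matrix(rnorm(80), 4, 20, dimnames = list(paste0("f", 1:4), NULL))
  x[2, ] <- x[1, ]  # duplicated feature
  r1 <- svm_rank(x, design, seed = 5)
  r2 <- svm_rank(x, design, seed = 5)
  expect_identical(r1, r2)
  # of the two identical features the lower row index is eliminated first,
  # so f1 ends up ranked worse than f2
  expect_gt(r1$rank[r1$metabolite_id == "f1"],
            r1$rank[r1$metabolite_id == "f2"])
})

test_that("permuted labels give chance-level single-feature accuracy", {
  set.seed(33)
  accs <- vapply(1:20, function(i) {
    x <- matrix(rnorm(8 * 24), 8, 24, dimnames = list(paste0("f", 1:8), NULL))
    design <- group_design(sample(rep(c("a", "b"), each = 12)))
    rk <- svm_rank(x, design, seed = i)
    cv <- crossval_classify(x[rk$metabolite_id[1], , drop = FALSE], design,
                            folds = 4, seed = i)
    cv$balanced_accuracy
  }, 0)
  expect_gt(mean(accs), 35)
  expect_lt(mean(accs), 65)
})

test_that("panels take the best-ranked metabolites per direction", {
  rk <- data.frame(rank = 1:4, metabolite_id = c("A", "B", "C", "D"),
                   importance_score = 4:1,
                   direction = c("up", "down", "up", "down"))
  p <- select_panel(rk, n_up = 1, n_down = 1)
  expect_identical(p$up_markers, "A")
  expect_identical(p$down_markers, "B")
  p2 <- select_panel(rk, n_up = 2, n_down = 0)
  expect_identical(p2$up_markers, c("A", "C"))
  expect_length(p2$down_markers, 0L)
  expect_warning(p3 <- select_panel(rk, n_up = 4, n_down = 2), "fewer")
  expect_identical(p3$up_markers, c("A", "C"))
  expect_error(select_panel(rk, n_up = 0, n_down = 0), "both zero")
})

test_that("cross-validated metrics are reproducible and internally consistent", {
  set.seed(34)
  design <- group_design(rep(c("ctl", "dis"), c(14, 10)),
                         sample_ids = paste0("s", 1:24))
  x <- matrix(rnorm(3 * 24), 3, 24, dimnames = list(paste0("f", 1:3), NULL))
  x[1, design$labels == "dis"] <- x[1, design$labels == "dis"] + 3
  m1 <- crossval_classify(x, design, folds = 5, seed = 9)
  m2 <- crossval_classify(x, design, folds = 5, seed = 9)
  expect_identical(m1, m2)
  expect_equal(m1$balanced_accuracy,
               (m1$sensitivity + m1$specificity) / 2, tolerance = 1e-9)
  cc <- m1$confusion
  expect_equal(m1$ppv * (cc["nTP"] + cc["nFP"]) / 100, cc[["nTP"]],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m1$npv * (cc["nTN"] + cc["nFN"]) / 100, cc[["nTN"]],
               tolerance = 1e-9, ignore_attr = TRUE)

  # column order must not change the folds or the metrics
  perm <- sample(24)
  design_p <- group_design(as.character(design$labels)[perm],
                           sample_ids = design$sample_ids[perm])
  m3 <- crossval_classify(x[, perm], design_p, folds = 5, seed = 9)
  expect_identical(m3$confusion, m1$confusion)
})

test_that("metric formulas reproduce a published-style confusion breakdown", {
  m <- classification_metrics(nTP = 35, nFN = 0, nTN = 19, nFP = 1)
  expect_equal(m$accuracy, 100 * 54 / 55, tolerance = 1e-9)  # 98.18%
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 95)
  expect_equal(m$balanced_accuracy, 97.5)
})

test_that("correlation networks threshold absolute Pearson correlation", {
  set.seed(36)
  x <- matrix(rnorm(5 * 30), 5, 30, dimnames = list(paste0("f", 1:5), NULL))
  x[2, ] <- x[1, ]
  net <- correlation_network(x, threshold = 0.999)
  expect_identical(nrow(net), 1L)
  expect_identical(c(net$id_a, net$id_b), c("f1", "f2"))
  expect_equal(net$pearson_r, 1)

  full <- correlation_network(x, threshold = 0)
  expect_identical(nrow(full), 10L)

  y <- rbind(x[1:3, ], const = rep(2, 30))
  expect_warning(net2 <- correlation_network(y, threshold = 0), "constant")
  expect_false("const" %in% c(net2$id_a, net2$id_b))

  # independent noise, n = 55: no |r| >= 0.7 edges expected
  z <- matrix(rnorm(6 * 55), 6, 55)
  expect_identical(nrow(correlation_network(z, threshold = 0.7)), 0L)
})
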