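# Dataset handling and the four classifiers.

test_that("stratified split reproduces the 2/3-1/3 proportions", {
  set.seed(99)
  x <- matrix(rnorm(1457 * 3), 1457, 3)
  d <- labeled_dataset(x, c(rep(1L, 729), rep(-1L, 728)))
  parts <- split_dataset(d, 2 / 3, seed = 5)
  expect_equal(nrow(parts$train$x), 971)
  expect_equal(nrow(parts$test$x), 486)
  expect_length(intersect(parts$train$ids, parts$test$ids), 0)
  expect_setequal(c(parts$train$ids, parts$test$ids), d$ids)
  # small balanced case: 2 of each class in train
  d6 <- labeled_dataset(matrix(rnorm(12), 6, 2), c(1, 1, 1, -1, -1, -1))
  p6 <- split_dataset(d6, 2 / 3, seed = 1)
  expect_equal(as.integer(table(p6$train$y)), c(2L, 2L))
  # determinism
  pA <- split_dataset(d, 2 / 3, seed = 7); pB <- split_dataset(d, 2 / 3, seed = 7)
  expect_identical(pA$train$ids, pB$train$ids)
  expect_error(split_dataset(labeled_dataset(matrix(0, 3, 1), c(1, 1, -1))),
               "at least 2")
})

test_that("feature standardization uses training statistics only", {
  set.seed(3)
  tr <- labeled_dataset(cbind(a = rnorm(50, 5, 2), b = rnorm(50), cst = rep(1, 50)),
                        rep(c(1L, -1L), 25))
  te <- labeled_dataset(cbind(a = rnorm(20, 9, 4), b = rnorm(20), cst = rep(1, 20)),
                        rep(c(1L, -1L), 10))
  st <- standardize_features(tr, te)
  expect_equal(colnames(st$train$x), c("a", "b"))        # constant dropped
  expect_equal(colnames(st$test$x), c("a", "b"))
  expect_equal(unname(colMeans(st$train$x)), c(0, 0), tolerance = 1e-12)
  # test transformed with train parameters, not its own
  expect_equal(unname(st$test$x[, "a"]),
               unname((te$x[, "a"] - st$params$mean["a"]) / st$params$sd["a"]))
  expect_gt(abs(mean(st$test$x[, "a"])), 0.1)
})

test_that("median imputation fills masked values from the training set", {
  tr <- labeled_dataset(cbind(a = c(1, 2, 3, NA), b = rep(NA_real_, 4)),
                        c(1L, 1L, -1L, -1L))
  te <- labeled_dataset(cbind(a = c(NA, 10), b = c(NA, NA)), c(1L, -1L))
  im <- impute_missing(tr, te)
  expect_equal(colnames(im$train$x), "a")    # all-NA column dropped
  expect_equal(unname(im$train$x[4, "a"]), 2)
  expect_equal(unname(im$test$x[1, "a"]), 2)
})

test_that("random forest learns the synthetic benchmark and is reproducible", {
  d <- gen_dataset(synth_spec(n_per_class = 120, p = 6, d = 3.5, seed = 31))
  parts <- split_dataset(d, 2 / 3, seed = 8)
  m1 <- train_random_forest(parts$train, M_try = 2, N_tree = 60, seed = 17)
  m2 <- train_random_forest(parts$train, M_try = 2, N_tree = 60, seed = 17)
  p1 <- predict(m1, parts$test); p2 <- predict(m2, parts$test)
  expect_identical(p1, p2)                              # bit-reproducible
  expect_gt(1 - test_per(m1, parts$test), 0.9)
  expect_lt(abs(rf_oob_error(m1) - test_per(m1, parts$test)), 0.12)
})

test_that("degenerate forests behave as documented", {
  x <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("f1", "f2")))
  one <- labeled_dataset(x, rep(1L, 20))
  expect_warning(m <- train_random_forest(one, M_try = 1, N_tree = 10, seed = 1),
                 "single-class")
  expect_true(all(predict(m, x)$label == 1L))
  expect_equal(rf_oob_error(m), 0)
  # vote arithmetic and the tie rule, on a hand-built forest
  leaf <- function(cls) list(var = NA_integer_, thr = NA_real_,
                             left = NA_integer_, right = NA_integer_,
                             pred = cls)
  fake <- structure(list(trees = c(rep(list(leaf(1L)), 127), rep(list(leaf(-1L)), 54)),
                         N_tree = 181L, feature_names = colnames(x)),
                    class = "rf_model")
  pr <- predict(fake, x[1:2, ])
  expect_equal(pr$score, rep(127 / 181, 2))
  expect_equal(pr$label, c(1L, 1L))
  tie <- structure(list(trees = c(rep(list(leaf(1L)), 5), rep(list(leaf(-1L)), 5)),
                        N_tree = 10L, feature_names = colnames(x)),
                   class = "rf_model")
  expect_equal(predict(tie, x[1, , drop = FALSE])$label, -1L)
})

test_that("OOB coverage matches bootstrap arithmetic", {
  d <- gen_dataset(synth_spec(n_per_class = 100, p = 4, d = 2, seed = 5))
  m <- train_random_forest(d, M_try = 2, N_tree = 80, seed = 2)
  # each sample is OOB for ~ (1 - 1/n)^n ~ exp(-1) of trees
  frac <- mean(m$oob_tot) / m$N_tree
  expect_lt(abs(frac - exp(-1)), 0.03)
})

test_that("permutation importance finds the informative feature and ignores noise", {
  d <- gen_dataset(synth_spec(n_per_class = 100, p = 6, d = 4, seed = 12))
  m <- train_random_forest(d, M_try = 2, N_tree = 60, seed = 3)
  imp <- rf_feature_importance(m, d, seed = 4)
  expect_equal(imp$feature[1], "f1")
  expect_lt(max(abs(imp$importance[imp$feature != "f1"])), 0.05)
  expect_equal(select_top(imp, 3), imp$feature[1:3])
  # ranking invariant to feature-column order
  perm <- c(4, 1, 6, 2, 3, 5)
  d2 <- labeled_dataset(d$x[, perm], d$y, d$ids)
  m2 <- train_random_forest(d2, M_try = 2, N_tree = 60, seed = 3)
  imp2 <- rf_feature_importance(m2, d2, seed = 4)
  expect_equal(imp2$feature[1], "f1")
})

test_that("tuning tie-break rules: test PER, then training PER, then smaller N_tree", {
  scan <- data.frame(N_tree = c(100L, 200L, 300L),
                     test_per = c(0.05, 0.05, 0.06),
                     train_oob_per = c(0.12, 0.08, 0.02))
  expect_equal(select_tuning_winner(scan, "N_tree"), 200L)   # rule (i)
  scan$train_oob_per <- c(0.08, 0.08, 0.02)
  expect_equal(select_tuning_winner(scan, "N_tree"), 100L)   # rule (ii)
  scan2 <- data.frame(M_try = c(15L, 40L), test_per = c(0.0288, 0.05),
                      train_oob_per = c(0.0824, 0.02))
  expect_equal(select_tuning_winner(scan2, "M_try"), 15L)
  expect_error(select_tuning_winner(scan2[0, ], "M_try"))
})

test_that("tune_rf returns singleton grids unchanged and a full scan table", {
  d <- gen_dataset(synth_spec(n_per_class = 60, p = 4, d = 3, seed = 21))
  parts <- split_dataset(d, 2 / 3, seed = 2)
  res <- tune_rf(parts$train, parts$test, M_try_grid = 2L,
                 N_tree_grid = 25L, seed = 6, N_tree_ref = 25L)
  expect_equal(res$M_try, 2L)
  expect_equal(res$N_tree, 25L)
  expect_equal(nrow(res$scan), 2L)
  # prefix evaluation agrees with retraining at the grid size
  res2 <- tune_rf(parts$train, parts$test, M_try_grid = 2L,
                  N_tree_grid = c(10L, 25L), seed = 6, N_tree_ref = 25L)
  direct <- train_random_forest(parts$train, M_try = 2L, N_tree = 10L, seed = 6)
  row10 <- res2$scan[res2$scan$stage == 2 & res2$scan$N_tree == 10, ]
  expect_equal(row10$test_per, test_per(direct, parts$test))
  expect_equal(row10$train_oob_per, rf_oob_error(direct))
})

test_that("k-NN follows the vote and tie conventions", {
  x <- matrix(c(0, 0, 1, 1, 4, 4, 5, 5), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("f1", "f2")))
  d <- labeled_dataset(x, c(1L, 1L, -1L, -1L))
  m1 <- train_knn(d, k = 1)
  expect_equal(predict(m1, x[2, , drop = FALSE])$label, 1L)
  m3 <- train_knn(d, k = 3)
  pr <- predict(m3, matrix(c(0.4, 0.4), 1, dimnames = list(NULL, c("f1", "f2"))))
  expect_equal(pr$label, 1L)
  expect_equal(pr$score, 2 / 3)
  # k = n reduces to the global majority
  d5 <- labeled_dataset(rbind(x, c(9, 9)), c(1L, 1L, -1L, -1L, -1L))
  mall <- train_knn(d5, k = 5)
  expect_true(all(predict(mall, x)$label == -1L))
  # vote tie -> class of the nearest neighbour
  m2 <- train_knn(d, k = 2)
  pr2 <- predict(m2, matrix(c(0.9, 0.9, 3.2, 3.2), 2, 2, byrow = TRUE,
                            dimnames = list(NULL, c("f1", "f2"))))
  expect_equal(pr2$label, c(1L, -1L))
  expect_error(train_knn(d, k = 0), ">= 1")
  expect_error(train_knn(d, k = 9), "exceeds")
})

test_that("C4.5 splits by gain ratio and prunes to a sensible size", {
  # perfectly separable on one feature: depth-1 tree, zero training error
  x <- cbind(f1 = c(1, 2, 3, 10, 11, 12), f2 = rnorm(6))
  d <- labeled_dataset(x, c(-1L, -1L, -1L, 1L, 1L, 1L))
  m <- train_c45(d)
  expect_false(m$root$leaf)
  expect_true(m$root$left$leaf && m$root$right$leaf)
  expect_equal(predict(m, d)$label, d$y)
  # hand table: best split must match exhaustive gain-ratio enumeration
  set.seed(7)
  x8 <- cbind(f1 = c(0.1, 0.4, 0.5, 0.8, 0.2, 0.9, 0.65, 0.3),
              f2 = c(5, 3, 9, 1, 7, 2, 8, 4))
  y8 <- c(-1L, -1L, 1L, 1L, -1L, 1L, 1L, -1L)
  d8 <- labeled_dataset(x8, y8)
  m8 <- train_c45(d8, pruning_confidence = 0.25)
  entropy <- function(p, n) {
    q <- p / n
    ifelse(q %in% c(0, 1) | n == 0, 0, -q * log2(q) - (1 - q) * log2(1 - q))
  }
  best <- list(gr = -Inf)
  for (f in 1:2) for (thr in sort(unique(x8[, f]))[-8]) {
    thr2 <- mean(c(thr, min(x8[x8[, f] > thr, f])))
    l <- y8[x8[, f] <= thr2]; r <- y8[x8[, f] > thr2]
    gain <- entropy(sum(y8 == 1), 8) -
      (length(l) * entropy(sum(l == 1), length(l)) +
       length(r) * entropy(sum(r == 1), length(r))) / 8
    si <- entropy(length(l), 8)
    gr <- if (gain > 1e-12) gain / si else -Inf
    if (gr > best$gr) best <- list(gr = gr, f = f, thr = thr2)
  }
  expect_equal(m8$root$f, best$f)
  expect_equal(m8$root$thr, best$thr)
})

test_that("gain ratio of a class-preserving split is zero", {
  # both sides carry the same class distribution: no information gain
  x <- cbind(f1 = c(1, 1, 2, 2), f2 = c(1, 2, 1, 2))
  y <- c(1L, -1L, 1L, -1L)
  m <- train_c45(labeled_dataset(x, y))
  # the tree cannot profit from f1 (class-preserving); it must split on f2
  expect_true(m$root$leaf || m$root$f == 2L)
})

test_that("SVM separates XOR with an RBF kernel and respects symmetry", {
  x <- matrix(c(0, 0, 1, 1, 0, 1, 1, 0), 4, 2,
              dimnames = list(NULL, c("f1", "f2")))
  d <- labeled_dataset(x, c(1L, 1L, -1L, -1L))
  m <- train_svm(d, sigma = 0.2, C = 100)
  expect_equal(predict(m, d)$label, d$y)
  # two-point problem: decision boundary passes through the midpoint
  x2 <- matrix(c(-1, 0, 1, 0), 2, 2, byrow = TRUE,
               dimnames = list(NULL, c("f1", "f2")))
  m2 <- train_svm(labeled_dataset(x2, c(1L, -1L)), sigma = 1, C = 10)
  mid <- matrix(c(0, 0), 1, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(unname(topscreen:::.svm_decision(m2, mid)), 0, tolerance = 1e-6)
  expect_equal(predict(m2, x2)$label, c(1L, -1L))
})

test_that("all four classifiers are invariant to a consistent feature permutation", {
  d <- gen_dataset(synth_spec(n_per_class = 40, p = 5, d = 3, seed = 77))
  parts <- split_dataset(d, 2 / 3, seed = 1)
  st <- standardize_features(parts$train, parts$test)
  perm <- c(3, 5, 1, 4, 2)
  permute <- function(ds) labeled_dataset(ds$x[, perm], ds$y, ds$ids)
  stp <- list(train = permute(st$train), test = permute(st$test))
  trp <- permute(parts$train); tep <- permute(parts$test)
  m_rf <- train_random_forest(parts$train, 2, 40, seed = 9)
  m_rf_p <- train_random_forest(trp, 2, 40, seed = 9)
  # forests see features in different sampling order, so compare accuracy-level
  expect_lt(abs(test_per(m_rf, parts$test) - test_per(m_rf_p, tep)), 0.06)
  expect_identical(predict(train_knn(st$train, 3), st$test)$label,
                   predict(train_knn(stp$train, 3), stp$test)$label)
  expect_identical(predict(train_svm(st$train, 1, 1), st$test)$label,
                   predict(train_svm(stp$train, 1, 1), stp$test)$label)
})
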