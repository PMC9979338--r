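test_that("the RBF-SVM separates blobs, errors on one class, scores toward Pre-MF", {
  set.seed(3)
  X <- rbind(matrix(rnorm(80, 3), 40, 2), matrix(rnorm(80, -3), 40, 2))
  y <- rep(c("PreMF", "PostMF"), each = 40)
  m <- train_score_classifier(X, y)
  sc <- predict(m, X)
  expect_identical(unname(attr(sc, "labels")), y)
  expect_true(all(sc[1:40] > 0) && all(sc[41:80] < 0))
  expect_error(train_score_classifier(X, rep("PreMF", 80)), "both classes")
  # duplicated feature column leaves predictions unchanged (kernel width
  # rescales with dimension)
  m2 <- train_score_classifier(cbind(X, X), y)
  expect_equal(as.vector(predict(m2, cbind(X, X))), as.vector(sc),
               tolerance = 1e-3)   # same kernel; libsvm convergence epsilon
})

test_that("balanced CV cost rewards separation and penalizes imbalance", {
  set.seed(4)
  Xs <- rbind(matrix(rnorm(100, 4), 50, 2), matrix(rnorm(100, -4), 50, 2))
  colnames(Xs) <- c("a", "b")
  ys <- rep(c("PreMF", "PostMF"), each = 50)
  expect_gt(balanced_cv_cost(Xs, ys, c("a", "b"), folds = 5, mc = 2), 0.95)
  # pure noise: chance within Monte-Carlo error
  Xn <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  cn <- balanced_cv_cost(Xn, ys, c("a", "b"), folds = 5, mc = 3)
  expect_lt(abs(cn - 0.5), 0.18)
  # imbalanced classes push the classifier to the majority: the penalty
  # pulls the cost well below the plain majority accuracy
  Xi <- matrix(rnorm(220), 110, 2, dimnames = list(NULL, c("a", "b")))
  yi <- rep(c("PreMF", "PostMF"), c(100, 10))
  ci <- balanced_cv_cost(Xi, yi, c("a", "b"), folds = 5, mc = 2)
  expect_lt(ci, 0.75)   # majority accuracy alone would be ~0.91
  expect_error(balanced_cv_cost(Xs, ys, character(0)), "non-empty")
})

test_that("forward selection finds a planted informative pair first", {
  set.seed(9)
  n <- 60
  pool <- candidate_pool()
  X <- matrix(rnorm(n * 133), n, 133, dimnames = list(NULL, pool$column))
  y <- rep(c("PreMF", "PostMF"), each = n / 2)
  planted <- "T4.RelAlpha"
  X[, planted] <- ifelse(y == "PreMF", 1.5, -1.5) + rnorm(n, sd = 0.4)
  sel <- wsfs_select(X, y, folds = 5, mc = 1, seed = 2, max_pairs = 3)
  expect_identical(sel$pairs$column[1], planted)
  expect_true(all(diff(c(0.5, sel$cost_trace)) > 0))
})

test_that("selection breaks cost ties by lowest pool index", {
  set.seed(10)
  n <- 40
  pool <- candidate_pool()[1:60, ]
  X <- matrix(rnorm(n * 60, sd = 0.05), n, 60,
              dimnames = list(NULL, pool$column))
  y <- rep(c("PreMF", "PostMF"), each = n / 2)
  strong <- ifelse(y == "PreMF", 2, -2)
  X[, 12] <- strong
  X[, 47] <- strong          # identical copy later in the pool
  sel <- wsfs_select(X, y, pool = pool, folds = 4, mc = 1, seed = 5,
                     max_pairs = 1)
  expect_identical(sel$pairs$column[1], pool$column[12])
})

test_that("all-noise pools terminate early near chance", {
  set.seed(12)
  n <- 50
  pool <- candidate_pool()[1:40, ]
  X <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, pool$column))
  y <- rep(c("PreMF", "PostMF"), each = n / 2)
  sel <- wsfs_select(X, y, pool = pool, folds = 5, mc = 2, seed = 3,
                     max_pairs = 8)
  expect_lte(nrow(sel$pairs), 3)
})

test_that("participant evaluation reports bounded, chance-consistent metrics", {
  ft <- planted_features()
  st <- ft$state
  Xpre <- ft$values[st == "PreMF", ]
  Xpost <- ft$values[st == "PostMF", ]
  sel <- wsfs_select(rbind(Xpre, Xpost),
                     rep(c("PreMF", "PostMF"), c(nrow(Xpre), nrow(Xpost))),
                     folds = 3, mc = 1, seed = 4, max_pairs = 3)
  ev <- evaluate_participant(Xpre, Xpost, sel, folds = 5, mc = 5, seed = 6)
  m <- ev$metrics
  # strong planted effect (delta = 0.5)
  expect_gt(m[["accuracy"]], 85)
  # algebraic identity for balanced classes
  expect_gte(m[["accuracy"]], min(m[["sensitivity"]], m[["specificity"]]) - 1e-9)
  expect_lte(m[["accuracy"]], max(m[["sensitivity"]], m[["specificity"]]) + 1e-9)
  expect_true(all(m[c("accuracy", "sensitivity", "specificity")] >= 0 &
                    m[c("accuracy", "sensitivity", "specificity")] <= 100))
  expect_length(ev$scores_pre, nrow(Xpre))
  # Pre-MF scores sit above Post-MF scores (positive = Pre-MF)
  expect_gt(mean(ev$scores_pre), mean(ev$scores_post))

  # permuted labels: held-out accuracy near chance
  set.seed(20)
  yperm <- sample(rep(c("PreMF", "PostMF"), c(nrow(Xpre), nrow(Xpost))))
  cost <- balanced_cv_cost(rbind(Xpre, Xpost), yperm,
                           sel$pairs$column, folds = 5, mc = 3)
  expect_lt(abs(cost - 0.5), 0.2)
})

test_that("the frozen ensemble scores flanking states deterministically", {
  ft <- planted_features()
  st <- ft$state
  Xpre <- ft$values[st == "PreMF", ]
  Xpost <- ft$values[st == "PostMF", ]
  X1 <- ft$values[st == "TaskRest1", ]
  X2 <- ft$values[st == "TaskRest2", ]
  ev <- evaluate_participant(Xpre, Xpost, c("O1.RelAlpha", "F3.RelBeta"),
                             folds = 3, mc = 3, seed = 2)
  f1 <- score_flanking_states(ev, X1, X2)
  f2 <- score_flanking_states(ev, X1, X2)
  expect_identical(f1, f2)
  expect_length(f1$taskrest1, nrow(X1))
  # TaskRest2 retains half the effect: its mean score falls between the
  # Pre-MF and Post-MF means
  expect_lt(mean(f1$taskrest2), mean(ev$scores_pre))
  expect_gt(mean(f1$taskrest2), mean(ev$scores_post))
  expect_error(score_flanking_states(ev, X1[, 1:5], X2), "feature mismatch")
})

test_that("occurrence summaries normalize to 100% per axis", {
  sel1 <- list(pairs = data.frame(channel = c("F3", "O1"),
                                  feature = c("TotalBeta", "RelAlpha")))
  sel2 <- list(pairs = data.frame(channel = "F3", feature = "TotalBeta"))
  occ <- occurrence_summary(list(sel1, sel2))
  expect_equal(sum(occ$features), 100, tolerance = 1e-9)
  expect_equal(sum(occ$channels), 100, tolerance = 1e-9)
  expect_equal(occ$features[["TotalBeta"]], 200 / 3, tolerance = 1e-9)
  expect_equal(occ$channels[["F3"]], 200 / 3, tolerance = 1e-9)
  # degenerate cohort: a single repeated pair occupies 100%
  occ1 <- occurrence_summary(list(sel2, sel2))
  expect_equal(occ1$features[["TotalBeta"]], 100)
  expect_equal(occ1$channels[["F3"]], 100)
  expect_warning(occ0 <- occurrence_summary(list()), "no selected pairs")
  expect_true(all(occ0$features == 0))
})
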