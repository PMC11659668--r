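test_that("the stratified split reproduces the 100/44 partition of 144 patients", {
  labels <- c(rep(1, 21), rep(0, 123))
  tr <- split_cohort(labels, 0.7, seed = 5)
  expect_equal(sum(tr), 100)
  expect_equal(sum(!tr), 44)
  expect_length(unique(labels[tr]), 2)
  expect_length(unique(labels[!tr]), 2)
  # positives allocated proportionally: round(0.7 * 21) = 15
  expect_equal(sum(labels[tr] == 1), 15)
  expect_identical(tr, split_cohort(labels, 0.7, seed = 5))
  expect_error(split_cohort(labels, 1.0, seed = 1), "train_frac")
  expect_error(split_cohort(rep(0, 50), 0.7, 1), "both classes")
})

test_that("the stepwise screen isolates a planted effect among correlated covariates", {
  keep_true <- 0
  keep_null <- 0
  for (s in 1:5) {
    set.seed(s + 40)
    n <- 250
    x1 <- rnorm(n)
    x2 <- 0.7 * x1 + sqrt(1 - 0.49) * rnorm(n)   # correlated proxy
    x3 <- rnorm(n)                                # pure noise
    y <- rbinom(n, 1, plogis(-1 + 1.2 * x1))
    sc <- screen_clinical(data.frame(x1 = x1, x2 = x2, x3 = x3), y,
                          enter_p = 0.05)
    keep_true <- keep_true + ("x1" %in% sc$multivariate$variable)
    keep_null <- keep_null + ("x3" %in% sc$multivariate$variable)
  }
  expect_gte(keep_true, 4)
  expect_lte(keep_null, 1)
})

test_that("screen reports odds ratios with Wald intervals", {
  set.seed(77)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1.5 + log(3) * x))
  sc <- screen_clinical(data.frame(x = x, z = rnorm(n)), y, enter_p = 0.05)
  uni <- sc$univariate
  orx <- uni$OR[uni$variable == "x"]
  expect_gt(orx, 1.8)
  expect_true(uni$ci_low[uni$variable == "x"] < orx &&
              orx < uni$ci_high[uni$variable == "x"])
})

test_that("classifiers reach AUC 1 on separable data and chance on permuted labels", {
  set.seed(9)
  n <- 100
  y <- rep(c(0, 1), each = n / 2)
  X <- data.frame(s = ifelse(y == 1, 2, -2) + rnorm(n, 0, 0.1),
                  noise = rnorm(n))
  for (algo in c("logistic", "random_forest", "gboost")) {
    b <- train_region_model(X, y, algorithm = algo, seed = 1)
    expect_equal(bedrad:::fast_auc(predict(b, X), y), 1.0)
  }
  yperm <- sample(y)
  bperm <- train_region_model(X, yperm, algorithm = "logistic", seed = 1)
  expect_gte(max(bperm$cv_auc), 0.30)
  expect_lte(max(bperm$cv_auc), 0.70)
})

test_that("grid search is deterministic and stays inside the declared grid", {
  set.seed(10)
  n <- 80
  y <- rbinom(n, 1, 0.5)
  X <- data.frame(a = y + rnorm(n), b = rnorm(n), c = rnorm(n))
  b1 <- train_region_model(X, y, algorithm = "random_forest", seed = 4)
  b2 <- train_region_model(X, y, algorithm = "random_forest", seed = 4)
  expect_identical(b1$hyperparameters, b2$hyperparameters)
  expect_identical(b1$cv_auc, b2$cv_auc)
  expect_true(nrow(merge(b1$hyperparameters, b1$grid)) == 1)
  expect_error(train_region_model(X[, 0], y), "empty feature set")
  p <- predict(b1, X)
  expect_true(all(p > 0 & p < 1))
})

test_that("algorithm comparison yields the same winner on rerun", {
  set.seed(20)
  n <- 90
  y <- rbinom(n, 1, 0.5)
  X <- data.frame(a = y + rnorm(n, 0, 0.8), b = rnorm(n))
  tr <- split_cohort(y, 0.7, seed = 1)
  r1 <- compare_algorithms(X, y, tr, algorithms = c("logistic", "svm_rbf",
                                                    "extra_trees"), seed = 2)
  r2 <- compare_algorithms(X, y, tr, algorithms = c("logistic", "svm_rbf",
                                                    "extra_trees"), seed = 2)
  expect_identical(attr(r1, "winner"), attr(r2, "winner"))
  expect_identical(r1$auc_val, r2$auc_val)
})

test_that("region fusion deduplicates and reruns the LASSO stage", {
  set.seed(30)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  X <- as.data.frame(matrix(rnorm(n * 6), n, 6,
                            dimnames = list(NULL, sprintf("R1__f%d", 1:6))))
  X[["R1__f1"]] <- y + rnorm(n, 0, 0.3)
  fz <- fuse_regions(list(R1 = c("R1__f1", "R1__f2"), R1b = c("R1__f1")), X, y)
  expect_equal(fz$pool, c("R1__f1", "R1__f2"))  # fused with itself: deduplicated
  expect_true("R1__f1" %in% fz$selected)
})

test_that("the dosimetric model is monotone in V_BED70", {
  set.seed(31)
  v <- runif(150, 0, 10)
  y <- rbinom(150, 1, plogis(-3 + 0.8 * v))
  dm <- build_dosimetric_model(v, y)
  expect_gt(dm$coefficient, 0)
  p <- predict(dm, sort(v))
  expect_true(all(diff(p) >= 0))
  expect_error(build_dosimetric_model(rep(1, 50), rbinom(50, 1, 0.5)),
               "zero variance")
})

test_that("a constant radiomic probability reduces the combined model to dosimetric", {
  set.seed(32)
  v <- runif(200, 0, 10)
  y <- rbinom(200, 1, plogis(-3 + 0.8 * v))
  dm <- build_dosimetric_model(v, y)
  cm <- build_combined_model(rep(0.5, 200), v, y)
  pc <- predict(cm, rep(0.5, 200), v)
  pd <- predict(dm, v)
  expect_gt(cor(pc, pd), 0.999)
})

test_that("out-of-fold probabilities are complete and honest", {
  set.seed(33)
  n <- 60
  y <- rbinom(n, 1, 0.5)
  X <- data.frame(a = y + rnorm(n), b = rnorm(n))
  oof <- oof_probabilities(X, y, "logistic", data.frame(dummy = 0), seed = 1)
  expect_length(oof, n)
  expect_false(any(is.na(oof)))
  expect_true(all(oof > 0 & oof < 1))
})

test_that("selection and training ignore validation rows entirely", {
  co_small <- make_leak_table()
  tab <- co_small$tab
  train <- co_small$train
  cas1 <- selection_cascade(tab[train, 3:12], tab$label[train], seed = 1)
  tab2 <- tab
  tab2$label[!train] <- sample(tab2$label[!train])
  cas2 <- selection_cascade(tab2[train, 3:12], tab2$label[train], seed = 1)
  expect_identical(cas1$selected, cas2$selected)
})
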