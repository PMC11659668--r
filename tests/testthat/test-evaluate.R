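test_that("AUC equals the concordant-pair fraction", {
  # 3 of the 4 positive-negative pairs are concordant
  ra <- roc_auc(c(0.1, 0.4, 0.5, 0.8), c(0, 1, 0, 1))
  expect_equal(ra$auc, 0.75)
  expect_equal(oracle_auc(c(0.1, 0.4, 0.5, 0.8), c(0, 1, 0, 1)), 0.75)
  expect_true(ra$ci[1] <= ra$auc && ra$auc <= ra$ci[2])
  expect_equal(roc_auc(c(0, 1, 0, 1, 1), c(0, 1, 0, 1, 1))$auc, 1.0)
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
  set.seed(13)
  for (r in 1:20) {
    n <- sample(8:30, 1)
    prob <- round(runif(n), 2)  # rounding forces ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(roc_auc(prob, y)$auc, oracle_auc(prob, y))
  }
})

test_that("label-independent scores give chance-level AUC at n = 1000", {
  set.seed(14)
  prob <- runif(1000)
  y <- rbinom(1000, 1, 0.3)
  auc <- roc_auc(prob, y)$auc
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
})

test_that("operating-point metrics match hand arithmetic and swap symmetry", {
  # TP 9, FN 3, FP 2, TN 31
  prob <- c(rep(0.9, 9), rep(0.1, 3), rep(0.9, 2), rep(0.1, 31))
  y <- c(rep(1, 12), rep(0, 33))
  m <- classification_metrics(prob, y, 0.5)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$specificity, 0.939, tolerance = 1e-3)
  expect_equal(m$PPV, 0.818, tolerance = 1e-3)
  expect_equal(m$NPV, 0.912, tolerance = 1e-3)
  expect_equal(m$accuracy, 40 / 45)
  # swapping labels and flipping scores swaps sens/spec and PPV/NPV
  m2 <- classification_metrics(1 - prob, 1 - y, 0.5)
  expect_equal(m2$sensitivity, m$specificity)
  expect_equal(m2$specificity, m$sensitivity)
  expect_equal(m2$PPV, m$NPV)
  expect_equal(m2$NPV, m$PPV)
})

test_that("all-correct predictions yield unit metrics and empty positives give NA PPV", {
  y <- c(rep(1, 5), rep(0, 5))
  m <- classification_metrics(c(rep(0.9, 5), rep(0.1, 5)), y, 0.5)
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity", "PPV", "NPV")]),
               setNames(rep(1, 5), c("accuracy", "sensitivity", "specificity", "PPV", "NPV")))
  m0 <- classification_metrics(rep(0.1, 10), y, 0.5)
  expect_true(is.na(m0$PPV))
  expect_error(classification_metrics(rep(0.1, 10), y, 1.5), "threshold")
})

test_that("Youden threshold maximizes sensitivity plus specificity", {
  set.seed(15)
  y <- rbinom(200, 1, 0.3)
  prob <- plogis(qlogis(0.3) + 2 * y + rnorm(200, 0, 1.2))
  th <- youden_threshold(prob, y)
  j <- function(t) {
    m <- classification_metrics(prob, y, t)
    m$sensitivity + m$specificity - 1
  }
  grid <- seq(0.02, 0.98, by = 0.02)
  expect_gte(j(th), max(vapply(grid, j, numeric(1))) - 1e-9)
})

test_that("Hosmer-Lemeshow calibration behaves across regimes", {
  # perfectly flat probabilities with matching outcome rate: statistic ~ 0
  set.seed(16)
  y <- rep(c(0, 1), 50)
  hl <- hosmer_lemeshow(rep(0.5, 100), y)
  expect_lt(hl$statistic, 1e-9)
  # well-calibrated probabilities: no significant miscalibration
  p <- runif(2000, 0.05, 0.95)
  yc <- rbinom(2000, 1, p)
  hc <- hosmer_lemeshow(p, yc)
  expect_gt(hc$p_value, 0.001)
  # systematically overconfident model: strong rejection at n = 1000
  po <- runif(1000, 0.05, 0.95)
  yo <- rbinom(1000, 1, 0.2 + 0.6 * (po > 0.5))
  pover <- plogis(3 * qlogis(po))
  ho <- hosmer_lemeshow(pover, yo)
  expect_lt(ho$p_value, 0.05)
  expect_error(hosmer_lemeshow(runif(10), rbinom(10, 1, 0.5)), "per bin")
})

test_that("decision-curve net benefit matches its closed forms", {
  set.seed(17)
  n <- 400
  y <- rbinom(n, 1, 0.25)
  prob <- plogis(qlogis(0.25) + 1.5 * (y - 0.25) + rnorm(n, 0, 0.5))
  dca <- decision_curve(prob, y)
  prev <- mean(y)
  expect_true(all(dca$net_benefit_none == 0))
  expect_equal(dca$net_benefit_all,
               prev - (1 - prev) * dca$threshold / (1 - dca$threshold),
               tolerance = 1e-12)
  expect_true(all(dca$net_benefit_model <= prev + 1e-12))
  # a perfect model attains the prevalence below every positive's probability
  perf <- ifelse(y == 1, 0.95, 0.05)
  dperf <- decision_curve(perf, y, thresholds = c(0.1, 0.5, 0.9))
  expect_equal(dperf$net_benefit_model[1:2], c(prev, prev))
  expect_error(decision_curve(prob, y, thresholds = c(0, 0.5)), "thresholds")
})

test_that("evaluation reports serialize with their curves", {
  set.seed(19)
  n <- 120
  y <- rbinom(n, 1, 0.3)
  prob <- plogis(qlogis(0.3) + 1.2 * y + rnorm(n))
  rep_ <- evaluation_report(prob, y, 0.3)
  path <- file.path(tempdir(), "evaluation.json")
  on.exit(unlink(c(path, paste0(path, c(".dca.csv", ".calibration.csv")))),
          add = TRUE)
  write_evaluation_report(rep_, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$auc, rep_$auc)
  dca <- read.csv(paste0(path, ".dca.csv"))
  expect_equal(dca$net_benefit_model, rep_$decision_curve$net_benefit_model)
})

test_that("the evaluation report assembles the full battery", {
  set.seed(18)
  n <- 150
  y <- rbinom(n, 1, 0.3)
  prob <- plogis(qlogis(0.3) + 1.5 * y + rnorm(n, 0, 1))
  th <- youden_threshold(prob, y)
  rep_ <- evaluation_report(prob, y, th)
  expect_true(rep_$auc >= 0 && rep_$auc <= 1)
  expect_true(rep_$auc_ci[1] <= rep_$auc && rep_$auc <= rep_$auc_ci[2])
  expect_true(all(unlist(rep_$metrics[c("sensitivity", "specificity")]) <= 1))
  expect_s3_class(rep_$decision_curve, "data.frame")
  expect_false(is.null(rep_$hosmer_lemeshow))
})
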