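#' ROC AUC with DeLong 95% confidence interval
#'
#' Trapezoidal AUC over the empirical ROC curve (mid-rank handling of tied
#' scores) with the DeLong variance estimate for the CI.
#'
#' @param probabilities predicted scores/probabilities.
#' @param labels binary labels (0/1).
#' @return list: `auc`, `ci` (length-2 vector, clipped to [0, 1]).
#' @export
roc_auc <- function(probabilities, labels) {
  if (length(unique(labels)) < 2) stop("both classes must be present")
  r <- pROC::roc(labels, probabilities, quiet = TRUE, direction = "<",
                 levels = c(0, 1))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  list(auc = as.numeric(pROC::auc(r)),
       ci = c(max(ci[1], 0), min(ci[3], 1)))
}

#' Youden-optimal operating threshold
#'
#' The probability cutoff maximizing sensitivity + specificity - 1 on the
#' given (training) data; frozen and reused for validation/test metrics.
#'
#' @inheritParams roc_auc
#' @return threshold in (0, 1).
#' @export
youden_threshold <- function(probabilities, labels) {
  cuts <- sort(unique(probabilities))
  if (length(cuts) > 1) cuts <- (cuts[-1] + cuts[-length(cuts)]) / 2
  j <- vapply(cuts, function(th) {
    pred <- probabilities >= th
    sens <- sum(pred & labels == 1) / sum(labels == 1)
    spec <- sum(!pred & labels == 0) / sum(labels == 0)
    sens + spec - 1
  }, numeric(1))
  cuts[which.max(j)]
}

#' Operating-point classification metrics
#'
#' Confusion-matrix accuracy, sensitivity, specificity, PPV and NPV at a
#' probability threshold (prediction positive iff probability >= threshold).
#' An empty predicted-positive set leaves PPV undefined (`NA`).
#'
#' @inheritParams roc_auc
#' @param threshold operating threshold in (0, 1).
#' @return named list: accuracy, sensitivity, specificity, PPV, NPV, and the
#'   confusion counts TP/FP/TN/FN.
#' @export
classification_metrics <- function(probabilities, labels, threshold) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  pred <- probabilities >= threshold
  tp <- sum(pred & labels == 1)
  fp <- sum(pred & labels == 0)
  tn <- sum(!pred & labels == 0)
  fn <- sum(!pred & labels == 1)
  list(accuracy = (tp + tn) / length(labels),
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       PPV = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       NPV = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Decile-of-risk binning; the statistic is
#' `sum((O - E)^2 / (E (1 - E / n_g)))` over bins, referred to a chi-squared
#' distribution with `bins - 2` degrees of freedom. Bins whose expected
#' count is zero are merged with their neighbour.
#'
#' @inheritParams roc_auc
#' @param bins number of risk bins (default 10).
#' @return list: `statistic`, `p_value`, `df`, `table` (per-bin n, observed,
#'   expected).
#' @export
hosmer_lemeshow <- function(probabilities, labels, bins = 10) {
  n <- length(probabilities)
  if (n < 2 * bins) stop("need at least 2 observations per bin")
  br <- unique(quantile(probabilities, probs = seq(0, 1, length.out = bins + 1),
                        type = 7))
  grp <- if (length(br) < 2) rep(1L, n)  # degenerate: constant probabilities
         else cut(probabilities, breaks = br, include.lowest = TRUE, labels = FALSE)
  tab <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    idx <- grp == g
    data.frame(n = sum(idx), observed = sum(labels[idx]),
               expected = sum(probabilities[idx]))
  }))
  # merge zero-expectation bins with the neighbour above
  while (any(tab$expected == 0) && nrow(tab) > 1) {
    i <- which(tab$expected == 0)[1]
    j <- if (i < nrow(tab)) i + 1 else i - 1
    tab[j, ] <- tab[i, ] + tab[j, ]
    tab <- tab[-i, , drop = FALSE]
    message("merged an empty Hosmer-Lemeshow bin with its neighbour")
  }
  O <- tab$observed; E <- tab$expected; ng <- tab$n
  denom <- E * (1 - E / ng)
  denom[denom < 1e-12] <- 1e-12
  stat <- sum((O - E)^2 / denom)
  df <- max(nrow(tab) - 2, 1)
  list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE),
       df = df, table = tab)
}

#' Decision curve analysis (net benefit)
#'
#' Net benefit of treating patients whose predicted probability exceeds a
#' threshold pt: `NB(pt) = TP/n - (FP/n) pt / (1 - pt)`, together with the
#' treat-all and treat-none (identically zero) reference strategies.
#'
#' @inheritParams roc_auc
#' @param thresholds probability threshold grid in (0, 1); default 0.01-0.60
#'   by 0.01 (the decision range relevant for SRP prophylaxis).
#' @return data.frame: threshold, net_benefit_model, net_benefit_all,
#'   net_benefit_none.
#' @export
decision_curve <- function(probabilities, labels,
                           thresholds = seq(0.01, 0.60, by = 0.01)) {
  if (any(thresholds <= 0) || any(thresholds >= 1))
    stop("thresholds must lie in (0, 1)")
  n <- length(labels)
  prev <- mean(labels == 1)
  nb <- vapply(thresholds, function(pt) {
    pred <- probabilities >= pt
    tp <- sum(pred & labels == 1)
    fp <- sum(pred & labels == 0)
    tp / n - (fp / n) * pt / (1 - pt)
  }, numeric(1))
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, net_benefit_model = nb,
             net_benefit_all = nb_all, net_benefit_none = 0)
}

#' Full evaluation battery for one model on one cohort
#'
#' AUC with DeLong CI, operating-point metrics at a frozen threshold,
#' Hosmer-Lemeshow calibration (when the cohort is large enough) and the
#' decision curve.
#'
#' @inheritParams roc_auc
#' @param threshold operating threshold (e.g. Youden-optimal on training).
#' @param hl_bins Hosmer-Lemeshow bins (skipped if the cohort is too small).
#' @return an `evaluation_report` list.
#' @export
evaluation_report <- function(probabilities, labels, threshold,
                              hl_bins = 10) {
  ra <- roc_auc(probabilities, labels)
  hl <- if (length(labels) >= 2 * hl_bins)
    hosmer_lemeshow(probabilities, labels, hl_bins) else NULL
  structure(list(auc = ra$auc, auc_ci = ra$ci,
                 metrics = classification_metrics(probabilities, labels, threshold),
                 threshold = threshold,
                 hosmer_lemeshow = hl,
                 decision_curve = decision_curve(probabilities, labels)),
            class = "evaluation_report")
}

#' Write an evaluation report to JSON with curve CSVs
#'
#' @param report an `evaluation_report`.
#' @param path output JSON path; the decision curve is written as
#'   `<path>.dca.csv` and the calibration table (when present) as
#'   `<path>.calibration.csv`.
#' @return `path`, invisibly.
#' @export
write_evaluation_report <- function(report, path) {
  out <- list(auc = report$auc, auc_ci = report$auc_ci,
              threshold = report$threshold,
              metrics = report$metrics,
              hosmer_lemeshow = if (!is.null(report$hosmer_lemeshow))
                report$hosmer_lemeshow[c("statistic", "p_value", "df")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  write.csv(report$decision_curve, paste0(path, ".dca.csv"), row.names = FALSE)
  if (!is.null(report$hosmer_lemeshow))
    write.csv(report$hosmer_lemeshow$table, paste0(path, ".calibration.csv"),
              row.names = FALSE)
  invisible(path)
}

#' @method print evaluation_report
#' @export
print.evaluation_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<evaluation_report> AUC %.3f [%.3f-%.3f]  acc %.3f sens %.3f spec %.3f\n",
              x$auc, x$auc_ci[1], x$auc_ci[2],
              m$accuracy, m$sensitivity, m$specificity))
  invisible(x)
}
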