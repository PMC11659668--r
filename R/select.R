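#' Univariate Welch t-test filter
#'
#' Keeps features whose two-sample Welch t-test p-value between the two label
#' classes is below `alpha`, computed on training rows only.
#'
#' @param X numeric matrix/data.frame of features (training rows).
#' @param y binary labels (0/1) for the same rows.
#' @param alpha significance threshold (default 0.05).
#' @return character vector of surviving feature names, with the p-values as
#'   a `p_values` attribute.
#' @export
ttest_filter <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present in the training split")
  g1 <- X[y == 1, , drop = FALSE]
  g0 <- X[y == 0, , drop = FALSE]
  n1 <- nrow(g1); n0 <- nrow(g0)
  m1 <- colMeans(g1); m0 <- colMeans(g0)
  v1 <- apply(g1, 2, var); v0 <- apply(g0, 2, var)
  se2 <- v1 / n1 + v0 / n0
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * pt(-abs(t), df)
  p[!is.finite(p)] <- 1  # zero-variance or degenerate features never pass
  keep <- colnames(X)[p < alpha]
  attr(keep, "p_values") <- setNames(p, colnames(X))
  keep
}

#' Pearson redundancy pruning
#'
#' Greedy recursive deletion: while any pair of surviving features has
#' `|r| > r_max`, remove the feature with the largest mean absolute
#' correlation to all current survivors (lexicographically later name on
#' ties). The surviving set has no pair above the threshold.
#'
#' @param X feature matrix (training rows).
#' @param kept candidate feature names.
#' @param r_max correlation threshold (default 0.9).
#' @return character vector of surviving features, with the deletion order
#'   as attribute `removed`.
#' @export
correlation_prune <- function(X, kept, r_max = 0.9) {
  if (length(kept) <= 1) {
    attr(kept, "removed") <- character(0)
    return(kept)
  }
  R <- abs(cor(as.matrix(X[, kept, drop = FALSE])))
  R[!is.finite(R)] <- 0
  diag(R) <- 0
  alive <- kept
  removed <- character(0)
  while (length(alive) > 1 && max(R[alive, alive]) > r_max) {
    sub <- R[alive, alive, drop = FALSE]
    meanabs <- rowMeans(sub)
    worst <- max(meanabs)
    cand <- alive[meanabs >= worst - 1e-15]
    victim <- sort(cand, decreasing = TRUE)[1]  # lexicographically later
    removed <- c(removed, victim)
    alive <- setdiff(alive, victim)
  }
  out <- kept[kept %in% alive]
  attr(out, "removed") <- removed
  out
}

#' Minimum-redundancy maximum-relevance selection
#'
#' Greedy forward mRMR, difference form, on correlation scales: relevance is
#' the absolute point-biserial correlation between feature and label (the
#' same ranking as the one-way F statistic, but bounded by 1), redundancy
#' the mean absolute Pearson correlation with already-selected features.
#' Putting both terms on the same bounded scale is what makes the
#' redundancy penalty effective — with raw F statistics (which run in the
#' hundreds) a near-duplicate of a selected feature would always beat a
#' weaker independent signal. The default cap is one-tenth of the training
#' sample size.
#'
#' @param X feature matrix (training rows).
#' @param y binary labels.
#' @param kept candidate feature names.
#' @param k number of features to select; default `floor(nrow(X) / 10)`.
#' @return character vector of `min(k, length(kept))` features in selection
#'   order, with greedy scores as attribute `scores`.
#' @export
mrmr_select <- function(X, y, kept, k = mrmr_default_k(nrow(X))) {
  if (k < 1) stop("k must be >= 1")
  kept <- as.character(kept)
  if (length(kept) == 0) return(character(0))
  Xm <- as.matrix(X[, kept, drop = FALSE])
  rel <- abs(suppressWarnings(cor(Xm, as.numeric(y))))[, 1]
  rel[!is.finite(rel)] <- 0
  names(rel) <- kept
  k <- min(k, length(kept))
  selected <- character(0)
  scores <- numeric(0)
  for (step in seq_len(k)) {
    rest <- setdiff(kept, selected)
    if (step == 1) {
      obj <- rel[rest]
    } else {
      red <- setNames(vapply(rest, function(f) {
        mean(abs(suppressWarnings(cor(Xm[, f], Xm[, selected, drop = FALSE]))),
             na.rm = TRUE)
      }, numeric(1)), rest)
      red[!is.finite(red)] <- 0
      obj <- rel[rest] - red
    }
    if (all(!is.finite(obj))) break
    best <- rest[which.max(obj)]
    selected <- c(selected, best)
    scores <- c(scores, max(obj))
  }
  attr(selected, "scores") <- setNames(scores, selected)
  selected
}

#' @rdname mrmr_select
#' @param n_train training sample size.
#' @export
mrmr_default_k <- function(n_train) max(1L, floor(n_train / 10))

# deterministic stratified fold assignment
stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

#' LASSO selection with cross-validated lambda
#'
#' L1-penalized logistic regression over glmnet's log-spaced lambda grid;
#' lambda is chosen by stratified 10-fold cross-validation minimizing the
#' mean squared error of the predicted probabilities against the 0/1 labels
#' (the minimum criterion). Features with nonzero coefficients at the chosen
#' lambda are returned together with the full CV trace.
#'
#' @param X feature matrix (training rows).
#' @param y binary labels.
#' @param kept candidate feature names.
#' @param folds number of CV folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param one_se use the 1-SE rule instead of the minimum criterion.
#' @return a `selection_report` stage list: `selected`, `coefficients`,
#'   `lambda`, `cv_lambda`, `cv_mse`, `cv_se`.
#' @export
lasso_select <- function(X, y, kept, folds = 10, seed = 1, one_se = FALSE) {
  if (length(kept) == 0)
    return(list(selected = character(0), coefficients = numeric(0),
                lambda = NA_real_, cv_lambda = numeric(0),
                cv_mse = numeric(0), cv_se = numeric(0)))
  Xm <- as.matrix(X[, kept, drop = FALSE])
  y <- as.numeric(y)
  if (length(y) < folds) stop("need at least `folds` training rows")
  if (length(kept) == 1) {
    # glmnet needs >= 2 columns; a single candidate is kept iff it survives
    # a univariate logistic fit (lambda path degenerates)
    fit <- glm(y ~ Xm, family = binomial())
    return(list(selected = kept, coefficients = setNames(coef(fit)[2], kept),
                lambda = 0, cv_lambda = numeric(0), cv_mse = numeric(0),
                cv_se = numeric(0)))
  }
  foldid <- stratified_folds(y, folds, seed)
  cv <- glmnet::cv.glmnet(Xm, y, family = "binomial", type.measure = "mse",
                          foldid = foldid, alpha = 1, standardize = FALSE)
  lam <- if (one_se) cv$lambda.1se else cv$lambda.min
  co <- as.matrix(coef(cv$glmnet.fit, s = lam))[, 1]
  co <- co[setdiff(names(co), "(Intercept)")]
  nz <- co[co != 0]
  list(selected = names(nz), coefficients = nz, lambda = lam,
       cv_lambda = cv$lambda, cv_mse = cv$cvm, cv_se = cv$cvsd)
}

#' Run the full four-stage selection cascade
#'
#' Welch t-test filter (p < alpha), Pearson redundancy pruning
#' (|r| <= r_max), mRMR cap at one-tenth of the sample size, then LASSO with
#' 10-fold cross-validated lambda. All statistics are computed on the
#' supplied (training) rows only. Stage outputs are nested subsets.
#'
#' @param X training-row feature matrix.
#' @param y training labels.
#' @param alpha t-test threshold.
#' @param r_max correlation threshold.
#' @param k mRMR cap.
#' @param folds,seed,one_se passed to [lasso_select()].
#' @return a `selection_report`: per-stage survivors, p-values, lambda trace
#'   and final coefficients.
#' @export
selection_cascade <- function(X, y, alpha = 0.05, r_max = 0.9,
                              k = mrmr_default_k(nrow(X)),
                              folds = 10, seed = 1, one_se = FALSE) {
  s1 <- ttest_filter(X, y, alpha)
  s2 <- correlation_prune(X, s1, r_max)
  s3 <- mrmr_select(X, y, s2, k)
  s4 <- lasso_select(X, y, s3, folds = folds, seed = seed, one_se = one_se)
  structure(list(input = colnames(X),
                 ttest = as.character(s1),
                 p_values = attr(s1, "p_values"),
                 pruned = as.character(s2),
                 removed = attr(s2, "removed"),
                 mrmr = as.character(s3),
                 mrmr_scores = attr(s3, "scores"),
                 lasso = s4,
                 selected = s4$selected),
            class = "selection_report")
}

#' Write a selection report to JSON plus a CV-trace CSV
#'
#' The JSON holds the per-stage surviving feature lists, p-values, pruning
#' order, mRMR scores and the chosen lambda with its nonzero coefficients;
#' the CSV holds the (lambda, CV MSE, SE) trace, ready for re-plotting the
#' regularization path.
#'
#' @param report a `selection_report` from [selection_cascade()].
#' @param path output JSON path; the trace is written as `<path>.cv.csv`.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  out <- list(ttest = report$ttest,
              p_values = as.list(report$p_values),
              pruned = report$pruned, removed = report$removed,
              mrmr = report$mrmr, mrmr_scores = as.list(report$mrmr_scores),
              lambda = report$lasso$lambda,
              coefficients = as.list(report$lasso$coefficients),
              selected = report$selected)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  if (length(report$lasso$cv_lambda))
    write.csv(data.frame(lambda = report$lasso$cv_lambda,
                         cv_mse = report$lasso$cv_mse,
                         cv_se = report$lasso$cv_se),
              paste0(path, ".cv.csv"), row.names = FALSE)
  invisible(path)
}

#' @method print selection_report
#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> %d -> %d (t-test) -> %d (pruning) -> %d (mRMR) -> %d (LASSO)\n",
              length(x$input), length(x$ttest), length(x$pruned),
              length(x$mrmr), length(x$selected)))
  if (length(x$selected)) cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
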