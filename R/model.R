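#' Stratified train/validation split
#'
#' Random split stratified by label. The training size is
#' `floor(train_frac * n)`, allocated across classes proportionally, which
#' reproduces the 100/44 split of a 144-patient cohort at 70%. If a split
#' would leave a single-class validation set, the next seed is tried (and
#' recorded).
#'
#' @param labels binary labels.
#' @param train_frac training fraction in (0, 1), default 0.7.
#' @param seed RNG seed.
#' @return logical vector, TRUE for training rows; attribute `seed_used`.
#' @export
split_cohort <- function(labels, train_frac = 0.7, seed = 1) {
  n <- length(labels)
  if (n < 10) stop("need at least 10 patients to split")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be in (0, 1): a degenerate split has no validation set")
  n_train <- floor(train_frac * n)
  seed_used <- seed
  repeat {
    set.seed(seed_used)
    pos <- which(labels == 1)
    neg <- which(labels == 0)
    n_pos_tr <- round(train_frac * length(pos))
    n_pos_tr <- min(max(n_pos_tr, 1L), length(pos) - 1L)
    n_neg_tr <- n_train - n_pos_tr
    n_neg_tr <- min(max(n_neg_tr, 1L), length(neg) - 1L)
    tr <- c(sample(pos, n_pos_tr), sample(neg, n_neg_tr))
    train <- seq_len(n) %in% tr
    if (length(unique(labels[train])) == 2 && length(unique(labels[!train])) == 2)
      break
    seed_used <- seed_used + 1L
    message("single-class split; retrying with seed ", seed_used)
  }
  attr(train, "seed_used") <- seed_used
  train
}

#' Univariate and stepwise multivariate clinical/dosimetric screen
#'
#' Each candidate variable is tested in a univariate logistic regression
#' (odds ratio, Wald 95% CI, p). Variables with univariate p below
#' `enter_p` (default 0.01) become candidates for a stepwise multivariate
#' logistic model (forward entry at `stay_p` with backward removal), the
#' stable choice when many DVH-derived candidates are nearly collinear.
#' Perfect separation of the final model is flagged and the fit falls back
#' to a ridge-penalized fit for reporting.
#'
#' @param data data.frame of numeric candidate variables.
#' @param labels binary outcome.
#' @param enter_p univariate entry threshold (default 0.01).
#' @param stay_p backward-elimination stay threshold (default 0.05).
#' @return a `screen_result`: `univariate` (data.frame: variable, OR,
#'   ci_low, ci_high, p), `candidates`, `multivariate` (same columns for
#'   retained variables), `separation_flag`.
#' @export
screen_clinical <- function(data, labels, enter_p = 0.01, stay_p = 0.05) {
  if (nrow(data) < 20) stop("need at least 20 patients for the screen")
  vars <- names(data)
  # Wald table of a logistic fit via glm.fit (fast path for the many
  # candidate fits); aliased columns get p = 1
  wald_fit <- function(cols) {
    X1 <- cbind(1, as.matrix(data[, cols, drop = FALSE]))
    colnames(X1) <- c("(Intercept)", cols)
    fit <- suppressWarnings(glm.fit(X1, labels, family = binomial()))
    k <- ncol(X1)
    se <- rep(NA_real_, k)
    piv <- fit$qr$pivot[seq_len(fit$rank)]
    covm <- chol2inv(fit$qr$qr[seq_len(fit$rank), seq_len(fit$rank), drop = FALSE])
    se[piv] <- sqrt(diag(covm))
    b <- fit$coefficients
    z <- b / se
    p <- 2 * pnorm(-abs(z))
    p[!is.finite(p)] <- 1
    list(coef = b[-1], se = se[-1], z = z[-1],
         p = setNames(p[-1], cols), fitted = fit$fitted.values)
  }
  uni <- do.call(rbind, lapply(vars, function(v) {
    x <- data[[v]]
    if (length(unique(x)) < 2 || sd(x) == 0)
      return(data.frame(variable = v, OR = NA, ci_low = NA, ci_high = NA, p = 1))
    w <- wald_fit(v)
    b <- w$coef[1]; se <- w$se[1]
    data.frame(variable = v, OR = exp(b), ci_low = exp(b - 1.96 * se),
               ci_high = exp(b + 1.96 * se), p = w$p[[v]])
  }))
  cand <- uni$variable[!is.na(uni$p) & uni$p < enter_p]
  sep_flag <- FALSE
  multi <- uni[0, ]
  if (length(cand)) {
    # forward stepwise with backward removal (the classic stepwise logistic
    # procedure): add the remaining candidate with the smallest Wald p while
    # it is below stay_p, then drop any retained term whose p rises above it
    alive <- character(0)
    term_p <- function(vars) wald_fit(vars)$p
    repeat {
      changed <- FALSE
      rest <- setdiff(cand, alive)
      if (length(rest)) {
        addp <- vapply(rest, function(v) term_p(c(alive, v))[[v]], numeric(1))
        if (min(addp) < stay_p) {
          alive <- c(alive, rest[which.min(addp)])
          changed <- TRUE
        }
      }
      while (length(alive)) {
        pv <- term_p(alive)
        if (max(pv) <= stay_p) break
        alive <- setdiff(alive, names(which.max(pv)))
        changed <- TRUE
      }
      if (!changed) break
    }
    if (length(alive)) {
      fit <- suppressWarnings(glm(labels ~ ., data = data[, alive, drop = FALSE],
                                  family = binomial()))
      if (any(abs(coef(fit)) > 15, na.rm = TRUE) ||
          any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10))
        sep_flag <- TRUE
    }
    if (length(alive)) {
      fit <- suppressWarnings(glm(labels ~ ., data = data[, alive, drop = FALSE],
                                  family = binomial()))
      if (sep_flag) {
        # ridge fallback keeps the report finite under separation
        Xm <- as.matrix(data[, alive, drop = FALSE])
        rfit <- glmnet::glmnet(cbind(Xm, 0), labels, family = "binomial",
                               alpha = 0, lambda = 0.01)
        br <- as.matrix(coef(rfit))[alive, 1]
        multi <- data.frame(variable = alive, OR = exp(br),
                            ci_low = NA, ci_high = NA, p = NA)
      } else {
        sm <- summary(fit)$coefficients
        rn <- intersect(rownames(sm), alive)
        multi <- data.frame(variable = rn,
                            OR = exp(sm[rn, 1]),
                            ci_low = exp(sm[rn, 1] - 1.96 * sm[rn, 2]),
                            ci_high = exp(sm[rn, 1] + 1.96 * sm[rn, 2]),
                            p = sm[rn, 4],
                            z = sm[rn, 3])
      }
    }
  }
  structure(list(univariate = uni, candidates = as.character(cand),
                 multivariate = multi, separation_flag = sep_flag),
            class = "screen_result")
}

# ---- classifier harness -----------------------------------------------------

# fast AUC by the rank (Mann-Whitney) formula with mid-rank ties
fast_auc <- function(prob, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Default hyperparameter grids
#' @param algorithm one of `"logistic"`, `"svm_rbf"`, `"random_forest"`,
#'   `"extra_trees"`, `"gboost"`.
#' @param p number of features (used for the SVM gamma default).
#' @return data.frame grid of hyperparameter combinations.
#' @export
default_grid <- function(algorithm, p = 1) {
  switch(algorithm,
    logistic = data.frame(lambda = c(0, 0.01, 0.1, 1)),
    svm_rbf = expand.grid(cost = c(0.1, 1, 10), gamma = c(1 / p, 0.01)),
    random_forest = expand.grid(num_trees = c(100, 300), max_depth = c(3, 0)),
    extra_trees = expand.grid(num_trees = c(100, 300), max_depth = c(3, 0)),
    gboost = expand.grid(nrounds = c(50, 100), max_depth = c(2, 3), eta = 0.1),
    stop("unknown algorithm: ", algorithm))
}

fit_algorithm <- function(X, y, algorithm, pars, seed) {
  X <- as.matrix(X)
  switch(algorithm,
    logistic = {
      # ridge-regularized logistic; lambda = 0 is the plain ML fit. At the
      # event counts typical here, shrinkage is what keeps many-feature
      # (fused) models from separating the training split.
      lam <- if (is.null(pars$lambda)) 0 else pars$lambda
      if (min(table(y)) < 2) lam <- 0  # glmnet needs two per class; glm does not
      if (lam == 0) {
        df <- data.frame(y = y, X)
        suppressWarnings(glm(y ~ ., data = df, family = binomial()))
      } else if (ncol(X) == 1) {
        structure(list(fit = suppressWarnings(
          glmnet::glmnet(cbind(X, 0), y, family = "binomial", alpha = 0,
                         lambda = lam)), pad = TRUE), class = "ridge1")
      } else {
        suppressWarnings(glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                                        lambda = lam))
      }
    },
    svm_rbf = e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "radial",
                         cost = pars$cost, gamma = pars$gamma,
                         probability = TRUE),
    random_forest = ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                                   probability = TRUE,
                                   num.trees = pars$num_trees,
                                   max.depth = pars$max_depth,
                                   seed = seed, num.threads = 1),
    extra_trees = ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                                 probability = TRUE, splitrule = "extratrees",
                                 num.trees = pars$num_trees,
                                 max.depth = pars$max_depth,
                                 seed = seed, num.threads = 1),
    gboost = {
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(X, label = y)
      xgboost::xgb.train(params = list(objective = "binary:logistic",
                                       max_depth = pars$max_depth,
                                       eta = pars$eta, nthread = 1),
                         data = dtrain, nrounds = pars$nrounds, verbose = 0)
    })
}

predict_prob_raw <- function(fit, algorithm, X) {
  X <- as.matrix(X)
  p <- switch(algorithm,
    logistic = {
      if (inherits(fit, "glm")) {
        as.numeric(predict(fit, newdata = data.frame(X), type = "response"))
      } else if (inherits(fit, "ridge1")) {
        as.numeric(predict(fit$fit, newx = cbind(X, 0), type = "response"))
      } else {
        as.numeric(predict(fit, newx = X, type = "response"))
      }
    },
    svm_rbf = {
      pr <- attr(predict(fit, X, probability = TRUE), "probabilities")
      as.numeric(pr[, "1"])
    },
    random_forest = as.numeric(predict(fit, data = X,
                                       num.threads = 1)$predictions[, "1"]),
    extra_trees = as.numeric(predict(fit, data = X,
                                     num.threads = 1)$predictions[, "1"]),
    gboost = as.numeric(predict(fit, X)))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Train one classifier with grid-searched hyperparameters
#'
#' Exhaustive grid search scored by stratified 5-fold cross-validated AUC on
#' the training rows, then a refit on the full training split with the best
#' hyperparameters.
#'
#' @param X training feature matrix (selected features only).
#' @param y training labels.
#' @param algorithm classifier family (see [default_grid()]).
#' @param grid hyperparameter grid; default from [default_grid()].
#' @param cv_folds CV folds for the grid search (default 5).
#' @param seed RNG seed (folds and stochastic learners).
#' @return a `model_bundle`: fitted model, algorithm, chosen hyperparameters,
#'   CV AUC per grid row, feature names.
#' @export
train_region_model <- function(X, y, algorithm = "logistic",
                               grid = default_grid(algorithm, ncol(X)),
                               cv_folds = 5, seed = 1) {
  if (is.null(ncol(X)) || ncol(X) == 0)
    stop("empty feature set: relax the selection cascade before training")
  X <- as.matrix(X)
  y <- as.numeric(y)
  foldid <- stratified_folds(y, cv_folds, seed)
  cv_auc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    prob <- rep(NA_real_, length(y))
    for (f in seq_len(cv_folds)) {
      tr <- foldid != f
      if (length(unique(y[tr])) < 2) next
      fit <- fit_algorithm(X[tr, , drop = FALSE], y[tr], algorithm, grid[gi, , drop = FALSE], seed)
      prob[!tr] <- predict_prob_raw(fit, algorithm, X[!tr, , drop = FALSE])
    }
    ok <- !is.na(prob)
    cv_auc[gi] <- fast_auc(prob[ok], y[ok])
  }
  best <- which.max(cv_auc)
  fit <- fit_algorithm(X, y, algorithm, grid[best, , drop = FALSE], seed)
  structure(list(algorithm = algorithm, fit = fit,
                 hyperparameters = grid[best, , drop = FALSE],
                 grid = grid, cv_auc = cv_auc,
                 features = colnames(X), seed = seed),
            class = "model_bundle")
}

#' Predicted event probabilities from a model bundle
#' @param object a `model_bundle`.
#' @param newdata feature matrix/data.frame containing the bundle's features.
#' @param ... unused.
#' @return probabilities in (0, 1).
#' @export
predict.model_bundle <- function(object, newdata, ...) {
  predict_prob_raw(object$fit, object$algorithm,
                   as.matrix(newdata[, object$features, drop = FALSE]))
}

#' @method print model_bundle
#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %s, %d features, best CV AUC %.3f\n",
              x$algorithm, length(x$features), max(x$cv_auc, na.rm = TRUE)))
  invisible(x)
}

#' Out-of-fold predicted probabilities on the training split
#'
#' Stratified k-fold refits with fixed hyperparameters; each training row is
#' predicted by the model that did not see it. Used to fit probability
#' stacking without rewarding base-model overfit.
#'
#' @param X training feature matrix.
#' @param y training labels.
#' @param algorithm classifier family.
#' @param pars hyperparameter row (e.g. a bundle's `hyperparameters`).
#' @param folds number of folds (default 5).
#' @param seed RNG seed.
#' @return out-of-fold probabilities aligned with the rows of `X`.
#' @export
oof_probabilities <- function(X, y, algorithm, pars, folds = 5, seed = 1) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  foldid <- stratified_folds(y, folds, seed)
  prob <- rep(NA_real_, length(y))
  for (f in seq_len(folds)) {
    tr <- foldid != f
    if (length(unique(y[tr])) < 2) tr <- rep(TRUE, length(y))
    fit <- fit_algorithm(X[tr, , drop = FALSE], y[tr], algorithm, pars, seed)
    prob[foldid == f] <- predict_prob_raw(fit, algorithm,
                                          X[foldid == f, , drop = FALSE])
  }
  prob
}

#' Fuse per-region selected features into a composite selection
#'
#' Concatenates the region-prefixed selected feature lists of the member
#' regions (deduplicated) and reruns the LASSO stage on the concatenation;
#' the result feeds [train_region_model()] for the composite (RA/RAP/RAPB)
#' models.
#'
#' @param selected_per_region named list: region -> selected feature names
#'   (already region-prefixed column names).
#' @param X training feature matrix containing all those columns.
#' @param y training labels.
#' @param folds,seed passed to [lasso_select()].
#' @return list: `pool` (concatenated candidates), `lasso` report,
#'   `selected`.
#' @export
fuse_regions <- function(selected_per_region, X, y, folds = 10, seed = 1) {
  pool <- unique(unlist(selected_per_region, use.names = FALSE))
  if (length(pool) == 0)
    return(list(pool = character(0),
                lasso = list(selected = character(0)), selected = character(0)))
  rep_ <- lasso_select(X, y, pool, folds = folds, seed = seed)
  sel <- rep_$selected
  if (length(sel) == 0) sel <- pool  # full shrinkage: keep the pooled candidates
  list(pool = pool, lasso = rep_, selected = sel)
}

#' Univariate dosimetric model (V_BED70 logistic regression)
#'
#' @param vbed70 V_BED70 values (percent of nontarget lung).
#' @param labels binary outcome.
#' @return a `dosimetric_model` (glm wrapper with `predict`).
#' @export
build_dosimetric_model <- function(vbed70, labels) {
  if (sd(vbed70) == 0) stop("V_BED70 has zero variance")
  fit <- suppressWarnings(glm(labels ~ vbed70, family = binomial()))
  structure(list(fit = fit, coefficient = coef(fit)[["vbed70"]]),
            class = "dosimetric_model")
}

#' @export
predict.dosimetric_model <- function(object, vbed70, ...) {
  p <- as.numeric(predict(object$fit, newdata = data.frame(vbed70 = vbed70),
                          type = "response"))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Combined radiomic + dosimetric model (probability stacking)
#'
#' Logistic regression of the outcome on the radiomic model's predicted
#' probability and V_BED70, fitted on the training split.
#'
#' @param radiomic_prob training predicted probabilities of the radiomic model.
#' @param vbed70 training V_BED70 values.
#' @param labels training labels.
#' @return a `combined_model`.
#' @export
build_combined_model <- function(radiomic_prob, vbed70, labels) {
  df <- data.frame(rp = qlogis(pmin(pmax(radiomic_prob, 1e-12), 1 - 1e-12)),
                   vbed70 = vbed70)
  fit <- suppressWarnings(glm(labels ~ ., data = df, family = binomial()))
  structure(list(fit = fit), class = "combined_model")
}

#' @export
predict.combined_model <- function(object, radiomic_prob, vbed70, ...) {
  df <- data.frame(rp = qlogis(pmin(pmax(radiomic_prob, 1e-12), 1 - 1e-12)),
                   vbed70 = vbed70)
  p <- as.numeric(predict(object$fit, newdata = df, type = "response"))
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}
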