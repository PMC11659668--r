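#' Run the full multiregional SRP modelling pipeline on a synthetic cohort
#'
#' End-to-end harness: feature extraction for the seven discrete regions,
#' stratified 70/30 split, z-score normalization fitted on training rows,
#' the four-stage selection cascade and a classifier per region, LASSO-fused
#' composite (RA/RAP/RAPB) models, the univariate V_BED70 dosimetric model
#' and the stacked combined model, all evaluated on training and validation
#' splits.
#'
#' @param cohort an `srp_cohort` from [generate_cohort()].
#' @param algorithm classifier family for the region models (default
#'   `"logistic"`; see [default_grid()] for the alternatives).
#' @param config a [feature_config()].
#' @param train_frac training fraction (default 0.7).
#' @param seed RNG seed for split, folds and stochastic learners.
#' @param resample_mm optional isotropic resampling before extraction.
#' @param table optional precomputed [build_feature_table()] result.
#' @return an `srp_study`: list with `table`, `train` (logical), `norm`
#'   parameters, `selection` per region, `models`, `probabilities`,
#'   `evaluation` (data.frame of AUCs), `threshold`.
#' @export
srp_pipeline <- function(cohort, algorithm = "logistic",
                         config = feature_config(), train_frac = 0.7,
                         seed = 1, resample_mm = NULL, table = NULL) {
  if (is.null(table)) table <- build_feature_table(cohort, config, resample_mm)
  composites <- attr(table, "composites")
  train <- split_cohort(table$label, train_frac, seed)
  norm <- zscore_fit_transform(table, train)
  tab <- norm$table
  y <- tab$label
  ytr <- y[train]
  Xtr <- tab[train, , drop = FALSE]

  selection <- list()
  models <- list()
  probs <- list()

  region_cols <- function(region) grep(paste0("^", region, "__"), names(tab), value = TRUE)

  for (rn in discrete_regions()) {
    cols <- region_cols(rn)
    if (length(cols) == 0) next
    rep_ <- selection_cascade(Xtr[, cols, drop = FALSE], ytr, seed = seed)
    sel <- rep_$selected
    if (length(sel) == 0) sel <- head(rep_$mrmr, 1)  # keep the region in play
    selection[[rn]] <- rep_
    if (length(sel) == 0) next
    bundle <- train_region_model(Xtr[, sel, drop = FALSE], ytr,
                                 algorithm = algorithm, seed = seed)
    models[[rn]] <- bundle
    probs[[rn]] <- predict(bundle, tab)
  }

  for (cn in names(composites)) {
    members <- composite_regions()[[cn]]
    per_region <- lapply(members, function(rn) {
      s <- selection[[rn]]$selected
      if (length(s) == 0) head(selection[[rn]]$mrmr, 1) else s
    })
    fz <- fuse_regions(per_region, Xtr, ytr, seed = seed)
    selection[[cn]] <- fz
    if (length(fz$selected) == 0) next
    bundle <- train_region_model(Xtr[, fz$selected, drop = FALSE], ytr,
                                 algorithm = algorithm, seed = seed)
    models[[cn]] <- bundle
    probs[[cn]] <- predict(bundle, tab)
  }

  vbed <- cohort$VBED70
  dosi <- build_dosimetric_model(vbed[train], ytr)
  probs[["dosimetric"]] <- predict(dosi, vbed)
  models[["dosimetric"]] <- dosi

  if (!is.null(probs[["RAPB"]])) {
    # the stacking logistic is fitted on out-of-fold base probabilities so an
    # overfit radiomic model cannot monopolize the combined model
    rapb <- models[["RAPB"]]
    oof <- oof_probabilities(Xtr[, rapb$features, drop = FALSE], ytr,
                             algorithm, rapb$hyperparameters, seed = seed)
    comb <- build_combined_model(oof, vbed[train], ytr)
    probs[["combined"]] <- predict(comb, probs[["RAPB"]], vbed)
    models[["combined"]] <- comb
  }

  evaluation <- do.call(rbind, lapply(names(probs), function(nm) {
    p <- probs[[nm]]
    data.frame(model = nm,
               auc_train = fast_auc(p[train], y[train]),
               auc_val = fast_auc(p[!train], y[!train]))
  }))

  structure(list(table = tab, train = train, norm = norm,
                 selection = selection, models = models,
                 probabilities = probs, evaluation = evaluation,
                 algorithm = algorithm, seed = seed),
            class = "srp_study")
}

#' @method print srp_study
#' @export
print.srp_study <- function(x, ...) {
  cat(sprintf("<srp_study> algorithm %s, %d train / %d validation\n",
              x$algorithm, sum(x$train), sum(!x$train)))
  print(x$evaluation, row.names = FALSE)
  invisible(x)
}

#' Compare classifier families on one selected feature set
#'
#' Trains every requested algorithm with its default grid on the training
#' rows and reports validation AUC; deterministic for a fixed seed.
#'
#' @param X feature matrix (all rows).
#' @param y labels.
#' @param train logical training index.
#' @param algorithms families to compare.
#' @param seed RNG seed.
#' @return data.frame: algorithm, auc_val, with attribute `winner`.
#' @export
compare_algorithms <- function(X, y, train,
                               algorithms = c("logistic", "svm_rbf",
                                              "random_forest", "extra_trees",
                                              "gboost"),
                               seed = 1) {
  res <- do.call(rbind, lapply(algorithms, function(a) {
    b <- train_region_model(X[train, , drop = FALSE], y[train],
                            algorithm = a, seed = seed)
    data.frame(algorithm = a, auc_val = fast_auc(predict(b, X)[!train], y[!train]))
  }))
  attr(res, "winner") <- res$algorithm[which.max(res$auc_val)]
  res
}
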