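align_drug_samples <- function(x, auc) {
  auc <- auc[!is.na(auc)]
  shared <- intersect(colnames(x), names(auc))
  if (!length(shared))
    stop("no overlap between feature matrix and AUC samples", call. = FALSE)
  list(x = x[, shared, drop = FALSE], auc = auc[shared])
}

#' Elastic-net regression of drug AUC on omics features
#'
#' Squared-error loss with elastic-net penalty (glmnet); features are
#' standardized internally and the training feature means are kept for
#' imputing missing features of new samples.
#'
#' @param x feature x sample matrix.
#' @param auc named AUC vector (NA = not assayed; samples intersected).
#' @param alpha elastic-net mixing parameter.
#' @param lambda penalty on glmnet's scale (the response is standardized
#'   internally, so the effective ridge shrinkage is `lambda / sd(auc)`);
#'   `NULL` picks the inner-CV minimum-RMSE lambda.
#' @param nfolds inner CV folds for lambda selection.
#' @param seed seed for the inner CV.
#' @return `drug_model` (kind "en") with the fit, `lambda`, `alpha`,
#'   `features` and training `feature_means`.
#' @export
fit_en_regression <- function(x, auc, alpha = 0.5, lambda = NULL,
                              nfolds = 5, seed = 1) {
  assert_matrix(x)
  d <- align_drug_samples(x, auc)
  X <- t(d$x)
  if (ncol(X) == 1)                    # glmnet requires >= 2 columns
    X <- cbind(X, `.zero` = 0)
  if (is.null(lambda)) {
    set.seed(as.integer(seed))
    cv <- glmnet::cv.glmnet(X, d$auc, alpha = alpha, nfolds = nfolds,
                            type.measure = "mse")
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    # include the requested lambda in the path so coefficients are exact
    lam_path <- exp(seq(log(max(lambda * 1e3, 1e-3)), log(lambda),
                        length.out = 40))
    fit <- glmnet::glmnet(X, d$auc, alpha = alpha, lambda = lam_path)
  }
  structure(list(kind = "en", fit = fit, alpha = alpha, lambda = lambda,
                 features = rownames(x), feature_means = rowMeans(d$x)),
            class = "drug_model")
}

#' Gradient-boosted-tree regression of drug AUC on omics features
#'
#' Stage-wise additive regression trees on squared loss (xgboost histogram
#' trees grown leaf-wise), with early stopping on an internal validation
#' split. Deterministic given the seed.
#'
#' @param x feature x sample matrix.
#' @param auc named AUC vector.
#' @param params list overriding the defaults: `nrounds` 500, `eta` 0.05,
#'   `max_leaves` 31, `early_stopping` 50, `valid_fraction` 0.2.
#' @param seed integer seed (validation split and any sampling).
#' @return `drug_model` (kind "gbt").
#' @export
fit_gbt_regression <- function(x, auc, params = list(), seed = 1) {
  assert_matrix(x)
  d <- align_drug_samples(x, auc)
  p <- utils::modifyList(list(nrounds = 500, eta = 0.05, max_leaves = 31,
                              early_stopping = 50, valid_fraction = 0.2),
                         params)
  set.seed(as.integer(seed))
  n <- ncol(d$x)
  X <- t(d$x)
  xgb_params <- list(objective = "reg:squarederror", eta = p$eta,
                     max_leaves = p$max_leaves, max_depth = 0,
                     grow_policy = "lossguide", tree_method = "hist",
                     nthread = 1, seed = as.integer(seed))
  n_valid <- floor(p$valid_fraction * n)
  if (n_valid >= 2 && stats::sd(d$auc) > 0) {
    vi <- sample.int(n, n_valid)
    dtrain <- xgboost::xgb.DMatrix(X[-vi, , drop = FALSE],
                                   label = d$auc[-vi])
    dvalid <- xgboost::xgb.DMatrix(X[vi, , drop = FALSE], label = d$auc[vi])
    booster <- xgboost::xgb.train(xgb_params, dtrain, nrounds = p$nrounds,
                                  evals = list(valid = dvalid),
                                  early_stopping_rounds = p$early_stopping,
                                  verbose = 0)
  } else {
    dtrain <- xgboost::xgb.DMatrix(X, label = d$auc)
    booster <- xgboost::xgb.train(xgb_params, dtrain, nrounds = p$nrounds,
                                  verbose = 0)
  }
  structure(list(kind = "gbt", fit = booster, params = p,
                 features = rownames(x), feature_means = rowMeans(d$x)),
            class = "drug_model")
}

#' Predict drug AUC for samples
#'
#' @param object a `drug_model`.
#' @param newdata feature x sample matrix; missing features or values are
#'   imputed with the training feature means.
#' @param ... unused.
#' @return named numeric vector of predicted AUCs.
#' @export
predict.drug_model <- function(object, newdata, ...) {
  assert_matrix(newdata)
  found <- intersect(object$features, rownames(newdata))
  if (!length(found)) stop("no shared features", call. = FALSE)
  X <- matrix(rep(object$feature_means, each = ncol(newdata)),
              ncol(newdata), length(object$features),
              dimnames = list(colnames(newdata), object$features))
  sub <- t(newdata[found, , drop = FALSE])
  miss <- is.na(sub)
  if (any(miss))
    sub[miss] <- rep(object$feature_means[found],
                     each = ncol(newdata))[miss]
  X[, found] <- sub
  if (object$kind == "en") {
    if (".zero" %in% rownames(object$fit$beta))
      X <- cbind(X, `.zero` = 0)
    as.numeric(predict(object$fit, X, s = object$lambda))
  } else {
    stats::setNames(predict(object$fit, xgboost::xgb.DMatrix(X)),
                    rownames(X))
  }
}

fit_drug_model <- function(x, auc, model = c("en", "gbt"), seed = 1, ...) {
  model <- match.arg(model)
  if (model == "en") fit_en_regression(x, auc, seed = seed, ...)
  else fit_gbt_regression(x, auc, seed = seed, ...)
}

#' Repeated cross-validated evaluation of a drug-response model
#'
#' Repeats `repeats` rounds of `folds`-fold cross-validation (default 5 x 5
#' = 25 training instances); each held-out fold contributes one row of
#' held-out Pearson r and RMSE, estimating how reproducibly the drug's AUC
#' can be modeled from the features.
#'
#' @param x feature x sample matrix.
#' @param auc named AUC vector (samples with NA dropped).
#' @param model `"en"` or `"gbt"`.
#' @param repeats,folds cross-validation geometry.
#' @param seed base seed (fold assignment and model fits).
#' @param ... passed to the fitting function.
#' @return data.frame with `repeats * folds` rows: rep, fold, r, rmse,
#'   n_test, n_features (signature size of that instance).
#' @export
repeated_cv_evaluate <- function(x, auc, model = c("en", "gbt"),
                                 repeats = 5, folds = 5, seed = 1, ...) {
  model <- match.arg(model)
  d <- align_drug_samples(x, auc)
  n <- ncol(d$x)
  if (n < folds) stop("need at least `folds` samples with AUC", call. = FALSE)
  rows <- list()
  for (rep_i in seq_len(repeats)) {
    set.seed(as.integer(seed) + rep_i)
    fold_id <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (stats::sd(d$auc[tr]) == 0) {
        warning("fold ", f, " rep ", rep_i,
                " skipped: zero variance in training AUC")
        next
      }
      fit <- fit_drug_model(d$x[, tr, drop = FALSE], d$auc[tr], model,
                            seed = as.integer(seed) + rep_i, ...)
      pred <- predict(fit, d$x[, !tr, drop = FALSE])
      obs <- d$auc[!tr]
      # a constant prediction carries no signal: score it r = 0 rather than
      # dropping the fold; r is NA only when the held-out AUCs are constant
      r <- if (stats::sd(obs) == 0) NA_real_
           else if (stats::sd(pred) == 0) 0
           else stats::cor(pred, obs)
      rows[[length(rows) + 1L]] <- data.frame(
        rep = rep_i, fold = f, r = r,
        rmse = sqrt(mean((pred - obs)^2)), n_test = sum(!tr),
        n_features = nrow(model_signature(fit)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

model_signature <- function(fit) {
  if (fit$kind == "en") {
    cf <- glmnet::coef.glmnet(fit$fit, s = fit$lambda)
    beta <- as.numeric(cf)[-1]
    nm <- rownames(cf)[-1]
    sel <- beta != 0 & nm != ".zero"
    data.frame(feature = nm[sel], weight = beta[sel])
  } else {
    imp <- xgboost::xgb.importance(model = fit$fit)
    if (is.null(imp) || !nrow(imp))
      data.frame(feature = character(), weight = numeric())
    else data.frame(feature = imp$Feature, weight = imp$Gain)
  }
}

#' Final per-drug feature signature
#'
#' Refits the chosen model on all samples with an observed AUC and extracts
#' its signature: nonzero coefficients (elastic net) or features with
#' positive importance (boosted trees).
#'
#' @param x feature x sample matrix.
#' @param auc named AUC vector.
#' @param model `"en"` or `"gbt"`.
#' @param seed seed for the refit.
#' @param ... passed to the fitting function.
#' @return data.frame with `feature` and `weight` (coefficient or gain).
#' @export
final_signature <- function(x, auc, model = c("en", "gbt"), seed = 1, ...) {
  fit <- fit_drug_model(x, auc, match.arg(model), seed = seed, ...)
  model_signature(fit)
}

#' Fold-ensemble AUC predictions for new samples
#'
#' Retrains the model on each of `folds` fold-complements of the training
#' cohort and predicts every new sample with each of the resulting models,
#' yielding a range of predictions per sample; the summary reports their
#' median, min and max.
#'
#' @param x_train training feature x sample matrix.
#' @param auc named training AUC vector.
#' @param model `"en"` or `"gbt"`.
#' @param new_matrix feature x sample matrix of new samples (missing
#'   features imputed with training means).
#' @param folds number of fold-complement models.
#' @param seed seed (fold split and fits).
#' @param ... passed to the fitting function.
#' @return list with `predictions` (new samples x folds matrix) and
#'   `summary` (data.frame: sample, median, min, max).
#' @export
predict_samples <- function(x_train, auc, model = c("en", "gbt"),
                            new_matrix, folds = 5, seed = 1, ...) {
  model <- match.arg(model)
  d <- align_drug_samples(x_train, auc)
  set.seed(as.integer(seed))
  fold_id <- sample(rep_len(seq_len(folds), ncol(d$x)))
  preds <- sapply(seq_len(folds), function(f) {
    fit <- fit_drug_model(d$x[, fold_id != f, drop = FALSE],
                          d$auc[fold_id != f], model, seed = seed, ...)
    predict(fit, new_matrix)
  })
  rownames(preds) <- colnames(new_matrix)
  colnames(preds) <- paste0("model", seq_len(folds))
  list(predictions = preds,
       summary = data.frame(sample = rownames(preds),
                            median = apply(preds, 1L, stats::median),
                            min = apply(preds, 1L, min),
                            max = apply(preds, 1L, max),
                            row.names = NULL))
}

#' Two-dimensional landscape of samples on a feature signature
#'
#' Embeds samples into 2-D using only the signature features — UMAP when the
#' uwot package is available, otherwise the first two principal components —
#' to visualize whether a signature separates sample groups. Deterministic
#' given the seed.
#'
#' @param m feature x sample matrix.
#' @param features signature feature ids (intersected with rownames).
#' @param seed integer seed.
#' @param n_neighbors UMAP neighborhood size (clipped to n - 1).
#' @param method `"umap"` (default when uwot is installed) or `"pca"`.
#' @return data.frame: sample, x, y.
#' @export
signature_landscape <- function(m, features = rownames(m), seed = 1,
                                n_neighbors = 15,
                                method = c("umap", "pca")) {
  assert_matrix(m)
  method <- match.arg(method)
  feats <- intersect(features, rownames(m))
  if (length(feats) < 2) stop("need >= 2 signature features", call. = FALSE)
  if (ncol(m) < 3) stop("need >= 3 samples", call. = FALSE)
  X <- t(m[feats, , drop = FALSE])
  if (method == "umap" && !requireNamespace("uwot", quietly = TRUE)) {
    warning("uwot not installed; falling back to PCA")
    method <- "pca"
  }
  if (method == "umap") {
    set.seed(as.integer(seed))
    emb <- uwot::umap(X, n_neighbors = min(n_neighbors, nrow(X) - 1),
                      n_threads = 1, n_sgd_threads = 0)
  } else {
    emb <- stats::prcomp(X, rank. = 2)$x
  }
  data.frame(sample = colnames(m), x = emb[, 1], y = emb[, 2],
             row.names = NULL)
}
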