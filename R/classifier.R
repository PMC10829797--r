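#' Fit a multinomial elastic-net subtype classifier
#'
#' Penalized multinomial regression of subtype labels on omics features,
#' minimizing the multinomial negative log-likelihood plus
#' `lambda * ((1 - alpha)/2 * ||beta||_2^2 + alpha * ||beta||_1)`, via glmnet
#' with the grouped multinomial penalty. Features are standardized with
#' training statistics that are stored in the model so external samples can
#' be projected (and their missing features mean-imputed) consistently.
#'
#' @param x feature x sample matrix (omics orientation; no NA).
#' @param labels subtype label per sample.
#' @param alpha elastic-net mixing parameter in [0, 1] (1 = lasso).
#' @param lambda penalty weight; `NULL` selects the minimizer of mean
#'   cross-validated multinomial deviance along glmnet's lambda path.
#' @param nfolds folds for the internal lambda-selection CV.
#' @param seed seed for the internal CV fold assignment.
#' @return `subtype_classifier` with the glmnet fit, `alpha`, `lambda`,
#'   `classes`, `features` and training `center`/`scale`.
#' @export
fit_multinomial_elasticnet <- function(x, labels, alpha = 0.9, lambda = NULL,
                                       nfolds = 5, seed = 1) {
  assert_matrix(x)
  labels <- as.factor(labels)
  if (length(labels) != ncol(x))
    stop("one label per sample required", call. = FALSE)
  if (any(table(labels) == 0) || nlevels(labels) < 2)
    stop("need >= 2 non-degenerate classes", call. = FALSE)
  X <- t(x)
  center <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = center, scale = scl)
  if (is.null(lambda)) {
    set.seed(as.integer(seed))
    cv <- glmnet::cv.glmnet(Xs, labels, family = "multinomial",
                            alpha = alpha, nfolds = nfolds,
                            type.multinomial = "grouped",
                            standardize = FALSE)
    lambda <- cv$lambda.min
    fit <- cv$glmnet.fit
  } else {
    # include the requested lambda in the path so coefficients are exact
    lam_path <- exp(seq(log(max(lambda * 1e3, 1e-3)), log(lambda),
                        length.out = 40))
    fit <- glmnet::glmnet(Xs, labels, family = "multinomial", alpha = alpha,
                          type.multinomial = "grouped", standardize = FALSE,
                          lambda = lam_path)
  }
  structure(list(fit = fit, alpha = alpha, lambda = lambda,
                 classes = levels(labels), features = rownames(x),
                 center = center, scale = scl),
            class = "subtype_classifier")
}

classifier_coefs <- function(model) {
  cf <- glmnet::coef.glmnet(model$fit, s = model$lambda)
  beta <- sapply(cf, function(b) as.numeric(b)[-1])
  rownames(beta) <- model$features
  list(beta = beta, intercept = vapply(cf, function(b) b[1], numeric(1)))
}

#' Predict subtype probabilities for new samples
#'
#' Projects new samples onto the model's feature space, standardizes, imputes
#' anything missing (values or whole features) to the feature mean — which is
#' zero after centering — and returns softmax class probabilities plus the
#' most likely subtype. `standardize = "training"` applies the training
#' cohort's center/scale (same-platform samples); `"self"` standardizes each
#' feature with the new cohort's own statistics, the procedure used when
#' transferring the model to external cell-line data.
#'
#' @param model a `subtype_classifier`.
#' @param newdata feature x sample matrix (NA allowed; extra features
#'   ignored, absent model features imputed).
#' @param standardize `"training"` or `"self"`.
#' @return list with `prob` (samples x classes, rows sum to 1) and `labels`.
#' @export
predict_proba <- function(model, newdata,
                          standardize = c("training", "self")) {
  standardize <- match.arg(standardize)
  assert_matrix(newdata)
  found <- intersect(model$features, rownames(newdata))
  if (!length(found)) stop("no overlapping features", call. = FALSE)
  n <- ncol(newdata)
  Xs <- matrix(0, n, length(model$features),
               dimnames = list(colnames(newdata), model$features))
  sub <- t(newdata[found, , drop = FALSE])
  if (standardize == "training") {
    sub <- scale(sub, center = model$center[found],
                 scale = model$scale[found])
  } else {
    ctr <- colMeans(sub, na.rm = TRUE)
    scl <- apply(sub, 2L, stats::sd, na.rm = TRUE)
    scl[!is.finite(scl) | scl == 0] <- 1
    ctr[!is.finite(ctr)] <- 0
    sub <- scale(sub, center = ctr, scale = scl)
  }
  sub[is.na(sub)] <- 0                    # mean imputation after centering
  Xs[, found] <- sub
  cf <- classifier_coefs(model)
  scores <- sweep(Xs %*% cf$beta, 2L, cf$intercept, `+`)
  colnames(scores) <- model$classes
  prob <- softmax(scores)
  labels <- factor(model$classes[max.col(prob, ties.method = "first")],
                   levels = model$classes)
  names(labels) <- colnames(newdata)
  list(prob = prob, labels = labels)
}

#' Stratified repeated cross-validation over an alpha grid
#'
#' For every elastic-net mixing value in `alpha_grid` and every repeat, the
#' samples are split into stratified folds (subtypes split equally across
#' folds); within each repeat, lambda is chosen to minimize the mean held-out
#' multinomial deviance along a shared path, and held-out error, per-class
#' recall/precision and the nonzero-feature count are recorded per fold.
#'
#' @param x feature x sample matrix.
#' @param labels subtype per sample; every class needs >= `folds` members.
#' @param alpha_grid mixing parameters to evaluate.
#' @param folds,repeats cross-validation geometry.
#' @param seed seed controlling fold assignment.
#' @return `cv_report` data.frame with one row per (alpha, repeat, fold):
#'   `error`, `recall_<class>`, `precision_<class>`, `nonzero`, `lambda`.
#' @export
cross_validate <- function(x, labels, alpha_grid = seq(0, 1, 0.1),
                           folds = 5, repeats = 5, seed = 1) {
  assert_matrix(x)
  labels <- as.factor(labels)
  if (any(table(labels) < folds))
    stop("every class needs >= folds samples", call. = FALSE)
  X <- t(scale(t(x)))
  classes <- levels(labels)
  rows <- list()
  for (a in alpha_grid) {
    for (rep_i in seq_len(repeats)) {
      set.seed(as.integer(seed) + rep_i)
      fold_id <- stratified_folds(labels, folds)
      fold_fits <- lapply(seq_len(folds), function(f) {
        tr <- fold_id != f
        fit <- glmnet::glmnet(t(X[, tr, drop = FALSE]), labels[tr],
                              family = "multinomial", alpha = a,
                              type.multinomial = "grouped",
                              standardize = FALSE, nlambda = 60)
        list(fit = fit, test = which(!tr))
      })
      lambdas <- sort(unique(unlist(lapply(fold_fits,
                                           function(ff) ff$fit$lambda))),
                      decreasing = TRUE)
      lambdas <- lambdas[seq(1, length(lambdas), length.out = 40)]
      # held-out deviance along the shared path, summed over folds
      dev <- sapply(fold_fits, function(ff) {
        pr <- predict(ff$fit, t(X[, ff$test, drop = FALSE]), s = lambdas,
                      type = "response")
        idx <- cbind(seq_along(ff$test), as.integer(labels[ff$test]))
        apply(pr, 3L, function(pp) -2 * sum(log(pmax(pp[idx], 1e-12))))
      })
      lam <- lambdas[which.min(rowSums(dev))]
      for (f in seq_len(folds)) {
        ff <- fold_fits[[f]]
        pr <- predict(ff$fit, t(X[, ff$test, drop = FALSE]), s = lam,
                      type = "response")[, , 1]
        pred <- factor(classes[max.col(pr, ties.method = "first")],
                       levels = classes)
        truth <- labels[ff$test]
        rec <- vapply(classes, function(cl) {
          n_cl <- sum(truth == cl)
          if (n_cl == 0) NA_real_ else sum(pred == cl & truth == cl) / n_cl
        }, numeric(1))
        prec <- vapply(classes, function(cl) {
          n_pr <- sum(pred == cl)
          if (n_pr == 0) NA_real_ else sum(pred == cl & truth == cl) / n_pr
        }, numeric(1))
        cf <- glmnet::coef.glmnet(ff$fit, s = lam)
        nz <- length(unique(unlist(lapply(cf, function(b)
          which(as.numeric(b)[-1] != 0)))))
        rows[[length(rows) + 1L]] <- data.frame(
          alpha = a, rep = rep_i, fold = f,
          error = mean(pred != truth),
          t(stats::setNames(rec, paste0("recall_", classes))),
          t(stats::setNames(prec, paste0("precision_", classes))),
          nonzero = nz, lambda = lam, check.names = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cv_report", class(out))
  out
}

#' Select the mixing parameter that rescues the hardest subtype
#'
#' The hardest class is the one with the lowest mean recall across the whole
#' report; the returned alpha maximizes that class's mean recall, breaking
#' ties toward the larger (sparser) alpha — the criterion that led to
#' alpha = 0.9 favouring the weakest subtype's recall.
#'
#' @param report a `cv_report` from [cross_validate()].
#' @return selected alpha (scalar).
#' @export
select_alpha <- function(report) {
  if (!nrow(report)) stop("empty report", call. = FALSE)
  rec_cols <- grep("^recall_", colnames(report), value = TRUE)
  class_means <- colMeans(report[rec_cols], na.rm = TRUE)
  hardest <- rec_cols[which.min(class_means)]
  by_alpha <- tapply(report[[hardest]], report$alpha,
                     mean, na.rm = TRUE)
  alphas <- as.numeric(names(by_alpha))
  best <- max(alphas[by_alpha == max(by_alpha)])
  best
}

#' Extract the classifier's feature signature
#'
#' Union over classes of features with a nonzero coefficient at the model's
#' lambda, annotated with the class(es) each feature is predictive of.
#'
#' @param model a `subtype_classifier`.
#' @return data.frame with `feature`, `classes` (comma-separated) and
#'   `n_classes`; zero rows when every coefficient is zero.
#' @export
extract_signature <- function(model) {
  cf <- classifier_coefs(model)
  nz <- lapply(model$classes, function(cl)
    model$features[cf$beta[, cl] != 0])
  names(nz) <- model$classes
  feats <- unique(unlist(nz))
  if (!length(feats))
    return(data.frame(feature = character(), classes = character(),
                      n_classes = integer()))
  membership <- vapply(feats, function(f)
    paste(model$classes[vapply(nz, function(v) f %in% v, logical(1))],
          collapse = ","), character(1))
  data.frame(feature = feats, classes = membership,
             n_classes = lengths(regmatches(membership,
                                            gregexpr(",", membership))) + 1L,
             row.names = NULL)
}
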