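# two linearly separable classes in two informative features
separable_toy <- function(n_per = 20, seed = 1, p_noise = 3) {
  set.seed(seed)
  x <- cbind(matrix(rnorm(2 * n_per, -2, 0.3), 2, n_per),
             matrix(rnorm(2 * n_per, 2, 0.3), 2, n_per))
  x <- rbind(x, matrix(rnorm(p_noise * 2 * n_per), p_noise))
  dimnames(x) <- list(paste0("f", seq_len(nrow(x))),
                      paste0("s", seq_len(ncol(x))))
  list(x = x, labels = factor(rep(c("A", "B"), each = n_per)))
}

test_that("a separable toy problem is fit to zero training error at small lambda", {
  toy <- separable_toy()
  model <- fit_multinomial_elasticnet(toy$x, toy$labels, alpha = 0.5,
                                      lambda = 1e-4)
  pred <- predict_proba(model, toy$x)
  expect_equal(as.character(pred$labels), as.character(toy$labels))
  expect_equal(unname(rowSums(pred$prob)), rep(1, ncol(toy$x)),
               tolerance = 1e-9)
})

test_that("the lasso end of the path is at least as sparse as ridge at equal lambda", {
  set.seed(2)
  x <- named_matrix(rnorm(40 * 30), 40)
  labels <- factor(rep(1:2, 15))
  lam <- 0.05
  n_nonzero <- function(alpha) {
    m <- fit_multinomial_elasticnet(x, labels, alpha = alpha, lambda = lam)
    nrow(extract_signature(m))
  }
  expect_lte(n_nonzero(1), n_nonzero(0))
  expect_equal(n_nonzero(0), 40)      # ridge keeps everything
})

test_that("the unpenalized limit matches a direct likelihood maximization", {
  set.seed(3)
  n <- 40
  x <- named_matrix(rnorm(2 * n), 2)
  eta <- 1.5 * x[1, ] - 0.8 * x[2, ]
  labels <- factor(ifelse(stats::runif(n) < stats::plogis(eta), "B", "A"))
  model <- fit_multinomial_elasticnet(x, labels, alpha = 0, lambda = 1e-6)
  pred <- predict_proba(model, x)

  # oracle: unpenalized binomial MLE by generic optimization
  Xs <- scale(t(x))
  nll <- function(b) {
    lin <- b[1] + Xs %*% b[2:3]
    -sum(ifelse(labels == "B", stats::plogis(lin, log.p = TRUE),
                stats::plogis(-lin, log.p = TRUE)))
  }
  opt <- stats::optim(c(0, 0, 0), nll, method = "BFGS")
  p_oracle <- as.numeric(stats::plogis(opt$par[1] + Xs %*% opt$par[2:3]))
  expect_equal(unname(pred$prob[, "B"]), p_oracle, tolerance = 0.01)
})

test_that("cross-validation is stratified, seeded and completely enumerated", {
  co <- small_cohort(seed = 4)
  om <- preprocess_cohort(co)
  report <- cross_validate(om$protein, co$truth_labels,
                           alpha_grid = c(0.1, 0.9), folds = 4, repeats = 2,
                           seed = 5)
  expect_s3_class(report, "cv_report")
  expect_equal(nrow(report), 2 * 2 * 4)
  expect_true(all(report$error >= 0 & report$error <= 1))

  # fold stratification: class counts per fold within 1 of proportionality
  labels <- co$truth_labels
  set.seed(as.integer(5) + 1L)
  fold_id <- proteosubtype:::stratified_folds(labels, 4)
  for (cl in unique(labels)) {
    per_fold <- table(factor(fold_id[labels == cl], levels = 1:4))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_error(cross_validate(om$protein, rep(1:4, c(45, 1, 1, 1)),
                              folds = 5), "folds")
})

test_that("high-SNR cohorts are classified nearly perfectly, pure noise at chance", {
  co <- small_cohort(seed = 6, noise_sd = 0.3)
  om <- preprocess_cohort(co)
  rep_hi <- cross_validate(om$protein, co$truth_labels, alpha_grid = 0.9,
                           folds = 4, repeats = 1, seed = 1)
  expect_lte(mean(rep_hi$error), 0.05)

  set.seed(7)
  x_noise <- named_matrix(rnorm(60 * 48), 60)
  labels <- factor(rep(1:4, each = 12))
  rep_null <- cross_validate(x_noise, labels, alpha_grid = 0.5,
                             folds = 4, repeats = 2, seed = 1)
  expect_gt(mean(rep_null$error), 0.5)   # chance level is 0.75
})

test_that("alpha selection maximizes the hardest class's recall with sparse tie-break", {
  rep_df <- expand.grid(alpha = c(0.1, 0.5, 0.9), rep = 1, fold = 1:2)
  rep_df$error <- 0.2
  rep_df$recall_1 <- 0.9
  rep_df$recall_2 <- c(0.5, 0.7, 0.6, 0.5, 0.7, 0.6)  # hardest; best at 0.5
  rep_df$nonzero <- 10
  class(rep_df) <- c("cv_report", class(rep_df))
  expect_equal(select_alpha(rep_df), 0.5)

  tie <- rep_df
  tie$recall_2 <- 0.6
  expect_equal(select_alpha(tie), 0.9)   # ties -> larger alpha
  single <- rep_df[rep_df$alpha == 0.1, ]
  expect_equal(select_alpha(single), 0.1)
  expect_error(select_alpha(rep_df[0, ]), "empty")
})

test_that("signatures collect nonzero features with class membership", {
  toy <- separable_toy(seed = 8)
  model <- fit_multinomial_elasticnet(toy$x, toy$labels, alpha = 1,
                                      lambda = 0.05)
  sig <- extract_signature(model)
  expect_true(all(c("f1", "f2") %in% sig$feature))
  expect_true(all(sig$n_classes >= 1))
  # grouped multinomial penalty selects features for all classes jointly
  expect_true(all(sig$classes == "A,B"))
  empty <- fit_multinomial_elasticnet(toy$x, toy$labels, alpha = 1,
                                      lambda = 1e3)
  expect_equal(nrow(extract_signature(empty)), 0)
  # signature size is non-increasing in lambda
  sizes <- vapply(c(0.001, 0.05, 0.3, 1e3), function(l)
    nrow(extract_signature(fit_multinomial_elasticnet(
      toy$x, toy$labels, alpha = 1, lambda = l))), numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("prediction handles centroids, missing features and intercept-only input", {
  co <- small_cohort(seed = 9, noise_sd = 0.3)
  om <- preprocess_cohort(co)
  model <- fit_multinomial_elasticnet(om$protein, co$truth_labels,
                                      alpha = 0.9, seed = 1)
  # class centroids are assigned to their class
  centroids <- sapply(1:4, function(st)
    rowMeans(om$protein[, co$truth_labels == st, drop = FALSE]))
  colnames(centroids) <- paste0("c", 1:4)
  pred <- predict_proba(model, centroids)
  expect_equal(as.integer(pred$labels), 1:4)

  # all features missing -> intercept-only softmax, identical for all samples
  blank <- matrix(NA_real_, nrow(om$protein), 2,
                  dimnames = list(rownames(om$protein), c("n1", "n2")))
  pb <- predict_proba(model, blank)
  expect_equal(pb$prob[1, ], pb$prob[2, ])
  expect_equal(unname(rowSums(pb$prob)), c(1, 1), tolerance = 1e-9)
  cf <- proteosubtype:::classifier_coefs(model)
  expect_equal(unname(pb$prob[1, ]),
               unname(exp(cf$intercept) / sum(exp(cf$intercept))),
               tolerance = 1e-9)
  # feature order does not matter
  shuf <- om$protein[sample(nrow(om$protein)), ]
  expect_equal(predict_proba(model, shuf)$prob, predict_proba(model, om$protein)$prob)
  expect_error(predict_proba(model, named_matrix(1, 1, "zzz")), "overlap")
})
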