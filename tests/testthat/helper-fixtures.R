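# Shared fixtures: small synthetic cohorts and matrices built in code.

small_cohort <- function(seed = 1, ...) {
  generate_cohort(synthetic_config(
    n_samples = 48, k_true = 4,
    n_features = c(mrna = 60, protein = 60, phospho = 40),
    n_plexes = 4, seed = seed, ...))
}

# cohort -> imputed, covariate-corrected matrices
preprocess_cohort <- function(cohort, covariates = c("loading_mass", "plex")) {
  lapply(cohort$omics, function(m) {
    m <- knn_impute(filter_missingness(m))
    eb_covariate_correction(m, cohort$annotation, covariates = covariates)
  })
}

named_matrix <- function(data, nrow, feature_prefix = "f",
                         sample_prefix = "s") {
  m <- matrix(data, nrow = nrow)
  dimnames(m) <- list(paste0(feature_prefix, seq_len(nrow)),
                      paste0(sample_prefix, seq_len(ncol(m))))
  m
}

# mean silhouette width over euclidean distances
mean_silhouette <- function(x, labels) {
  d <- as.matrix(stats::dist(x))
  mean(vapply(seq_along(labels), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_along(labels) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

# consensus labels renumbered to best match reference labels (majority vote)
match_labels <- function(labels, reference) {
  mapping <- vapply(sort(unique(labels)), function(cl) {
    as.integer(names(which.max(table(reference[labels == cl]))))
  }, integer(1))
  mapping[labels]
}
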