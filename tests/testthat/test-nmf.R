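test_that("signed split doubles rows, stays nonnegative and reconstructs the z-scores", {
  set.seed(1)
  mats <- list(mrna = named_matrix(rnorm(60), 10, "m"),
               protein = named_matrix(rnorm(60), 10, "p"),
               phospho = named_matrix(rnorm(60), 10, "q"))
  sp <- standardize_and_split(mats)
  expect_equal(nrow(sp$X), 60)
  expect_true(all(sp$X >= 0))
  for (mod in names(mats)) {
    z <- t(scale(t(mats[[mod]])))
    pos <- sp$X[sp$provenance$modality == mod &
                  sp$provenance$sign == "pos", ]
    neg <- sp$X[sp$provenance$modality == mod &
                  sp$provenance$sign == "neg", ]
    expect_equal(unname(pos - neg), unname(z), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_true(all(pos * neg == 0))       # disjoint supports
  }
})

test_that("signed split z-scores rows, drops constants and aligns shared samples", {
  m <- named_matrix(c(1, 1, 5, -1, 1, 3), nrow = 3)   # f2 is constant
  expect_warning(sp <- standardize_and_split(list(a = m)), "zero-variance")
  expect_equal(nrow(sp$X), 4)
  z1 <- sp$X["a|f1|pos", ] - sp$X["a|f1|neg", ]
  expect_equal(unname(z1), unname(as.numeric(scale(m[1, ]))))
  m2 <- m[, 1, drop = FALSE]
  expect_error(standardize_and_split(list(a = m, b = m2[, 0])), "shared")
})

test_that("rank-1 matrices are recovered exactly at k = 1", {
  X <- outer(c(2, 1), c(1, 2))
  dimnames(X) <- list(c("f1", "f2"), c("s1", "s2"))
  fit <- nmf_factorize(X, 1, seed = 2, max_iter = 2000, tol = 1e-12)
  expect_lt(max(abs(fit$W %*% fit$H - X)) / max(X), 1e-3)
})

test_that("the KL objective is monotone non-increasing and runs are seeded", {
  set.seed(3)
  X <- named_matrix(matrix(rexp(300), 20), 20)
  fit <- nmf_factorize(X, 3, seed = 7, max_iter = 150, tol = 0,
                       track_objective = TRUE)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  fit2 <- nmf_factorize(X, 3, seed = 7, max_iter = 150, tol = 0)
  expect_equal(fit$W, fit2$W)
  expect_equal(fit$H, fit2$H)
  expect_error(nmf_factorize(X, 0), "k must")
  expect_error(nmf_factorize(X, 25), "k must")
})

test_that("cluster assignment takes the H argmax with documented tie-breaks", {
  H <- matrix(c(0.9, 0.1, 0, 0,
                0.5, 0.5, 0, 0,
                0, 0.2, 0.8, 0), 4, 3)
  dimnames(H) <- list(paste0("metagene", 1:4), paste0("s", 1:3))
  fit <- structure(list(H = H), class = "nmf_fit")
  expect_equal(unname(assign_clusters(fit)), c(1, 1, 3))
  # permutation equivariance
  perm <- c(3, 1, 2, 4)
  fitp <- structure(list(H = H[perm, ]), class = "nmf_fit")
  expect_equal(unname(perm[assign_clusters(fitp)]),
               unname(assign_clusters(fit)))
  H0 <- H; H0[, 2] <- 0
  expect_error(assign_clusters(structure(list(H = H0), class = "nmf_fit")),
               "all-zero")
})

test_that("consensus over well-separated blocks is block diagonal with unit diagonal", {
  set.seed(4)
  blocks <- cbind(matrix(rep(c(5, 0), each = 10), 20, 8),
                  matrix(rep(c(0, 5), each = 10), 20, 8))
  blocks <- blocks + matrix(abs(rnorm(320, 0, 0.01)), 20)
  dimnames(blocks) <- list(paste0("f", 1:20), paste0("s", 1:16))
  cc <- consensus_cluster(blocks, 2, n_runs = 10, seed = 1)
  expect_true(isSymmetric(cc$A))
  expect_equal(unname(diag(cc$A)), rep(1, 16))
  truth <- rep(1:2, each = 8)
  expect_true(all(cc$A[truth == 1, truth == 1] > 0.99))
  expect_true(all(cc$A[truth == 1, truth == 2] < 0.01))
  expect_equal(cc$cophenetic_corr, 1, tolerance = 1e-9)
  # single run gives a 0/1 matrix
  one <- consensus_cluster(blocks, 2, n_runs = 1, seed = 1)
  expect_true(all(one$A %in% c(0, 1)))
})

test_that("cophenetic correlation matches a brute-force average-linkage oracle", {
  set.seed(5)
  n <- 8
  A <- matrix(runif(n * n, 0.2, 0.9), n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  dimnames(A) <- list(paste0("s", 1:n), paste0("s", 1:n))

  # naive agglomerative average linkage tracking pairwise merge heights
  D <- 1 - A
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  Dm <- D; diag(Dm) <- Inf
  coph <- matrix(0, n, n)
  Dwork <- Dm
  while (sum(active) > 1) {
    idx <- which(Dwork == min(Dwork[active, active]), arr.ind = TRUE)[1, ]
    i <- idx[1]; j <- idx[2]
    h <- Dwork[i, j]
    for (a in members[[i]]) for (b in members[[j]]) {
      coph[a, b] <- h; coph[b, a] <- h
    }
    merged <- c(members[[i]], members[[j]])
    # average linkage: mean pairwise distance between original members
    for (k in which(active)) {
      if (k %in% c(i, j)) next
      Dwork[i, k] <- Dwork[k, i] <-
        mean(D[merged, members[[k]], drop = FALSE])
    }
    members[[i]] <- merged
    active[j] <- FALSE
    Dwork[j, ] <- Inf; Dwork[, j] <- Inf
  }
  expected <- stats::cor(as.dist(D), as.dist(coph))
  expect_equal(cophenetic_correlation(A), expected, tolerance = 1e-10)

  # invariant to simultaneous row/column permutation
  perm <- sample(n)
  expect_equal(cophenetic_correlation(A[perm, perm]),
               cophenetic_correlation(A), tolerance = 1e-12)
  # constant consensus is undefined
  expect_true(is.na(cophenetic_correlation(matrix(1, 4, 4))))
})

test_that("select_k recovers a planted two-cluster structure at high SNR", {
  co <- generate_cohort(synthetic_config(
    n_samples = 40, k_true = 2, noise_sd = 0.3, missing_rate = 0,
    mnar_strength = 0, plex_offset_sd = 0, loading_mass_slope_mean = 0,
    loading_mass_slope_sd = 0,
    n_features = c(mrna = 40, protein = 40, phospho = 30), seed = 8))
  sp <- standardize_and_split(co$omics)
  sel <- select_k(sp, k_range = 2:4, n_runs = 8, seed = 1)
  expect_equal(sel$k_best, 2)
  expect_equal(nrow(sel$curve), 3)
  expect_true(all(is.finite(sel$curve$cophenetic)))
})

test_that("consensus labels are invariant (up to renumbering) under sample reordering", {
  co <- small_cohort(seed = 9)
  om <- preprocess_cohort(co)
  sp <- standardize_and_split(om)
  cc <- consensus_cluster(sp, 4, n_runs = 6, seed = 2)
  set.seed(10)
  perm <- sample(ncol(sp$X))
  Xp <- sp$X[, perm]
  ccp <- consensus_cluster(Xp, 4, n_runs = 6, seed = 2)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(cc$labels[colnames(Xp)],
                                         ccp$labels), 1)
})
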