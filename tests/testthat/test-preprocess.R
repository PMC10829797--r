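test_that("relative abundance is the zero-centered log2 ratio to the reference", {
  x <- named_matrix(c(4, 8, 1, 2, 2, 2), nrow = 2)
  colnames(x) <- c("s1", "s2", "ref")
  out <- relative_abundance(x, "ref")
  expect_equal(out["f1", ], c(s1 = 1, s2 = -1))
  expect_equal(out["f2", ], c(s1 = 1, s2 = -1))       # [2,0] centered

  eq <- named_matrix(rep(3, 6), nrow = 2)
  colnames(eq) <- c("s1", "s2", "ref")
  expect_true(all(relative_abundance(eq, "ref") == 0))

  bad <- named_matrix(c(4, 1, 0), nrow = 1)
  colnames(bad) <- c("s1", "s2", "ref")
  expect_true(all(is.na(relative_abundance(bad, "ref"))))
  expect_error(relative_abundance(x, "nope"), "reference")
})

test_that("row means of relative abundance are zero over observed entries", {
  set.seed(1)
  x <- named_matrix(exp(rnorm(60)), nrow = 10)
  colnames(x)[6] <- "ref"
  x[sample(60, 8)] <- NA
  x[, "ref"] <- exp(rnorm(10))
  out <- relative_abundance(x, "ref")
  expect_lt(max(abs(rowMeans(out, na.rm = TRUE))), 1e-9)
})

test_that("missingness filter keeps the inclusive boundary and preserves order", {
  m <- named_matrix(1, nrow = 4, feature_prefix = "g")
  m <- cbind(m, m, m, m)
  colnames(m) <- paste0("s", 1:4)
  m["g1", 1:3] <- NA         # 75% missing -> removed
  m["g2", 1:2] <- NA         # exactly 50% -> retained
  m["g3", 1] <- NA
  out <- filter_missingness(m, 0.5)
  expect_identical(rownames(out), c("g2", "g3", "g4"))
  expect_identical(out, m[c("g2", "g3", "g4"), ])
  # stricter threshold keeps a subset
  expect_lte(nrow(filter_missingness(m, 0.25)), nrow(out))
})

test_that("median polish removes additive row/column structure", {
  m <- named_matrix(c(1, 3, 2, 4), nrow = 2)
  expect_equal(unname(median_polish(m)), matrix(0, 2, 2))
  z <- named_matrix(0, nrow = 3)
  z <- cbind(z, z)
  colnames(z) <- paste0("s", 1:2)
  expect_true(all(median_polish(z) == 0))

  set.seed(2)
  r <- named_matrix(rnorm(200), nrow = 20)
  res <- median_polish(r, max_iter = 200, tol = 1e-8)
  expect_lt(max(abs(apply(res, 1, stats::median))), 1e-3)
  expect_lt(max(abs(apply(res, 2, stats::median))), 1e-3)
  # idempotence up to the convergence tolerance
  res2 <- median_polish(res, max_iter = 200, tol = 1e-8)
  expect_lt(max(abs(res2 - res)), 1e-3)
})

test_that("median polish tolerates NA and offers per-axis centering", {
  set.seed(3)
  m <- named_matrix(rnorm(60), nrow = 6)
  m[2, 3] <- NA
  res <- median_polish(m)
  expect_true(is.na(res[2, 3]))
  expect_equal(sum(is.na(res)), 1)
  ctr <- median_polish(m, method = "center")
  expect_lt(max(abs(apply(ctr, 2, stats::median, na.rm = TRUE))), 1e-12)
})

test_that("plex completeness filter follows the strict and relaxed rules", {
  m <- named_matrix(rnorm(24), nrow = 4)
  plex <- rep(1:3, each = 2)
  m["f2", 1:2] <- NA          # fully missing in plex 1
  m["f3", 1] <- NA            # partially missing -> still observed in plex 1
  strict <- plex_completeness_filter(m, plex, 0)
  expect_identical(rownames(strict), c("f1", "f3", "f4"))
  relaxed <- plex_completeness_filter(m, plex, 1)
  expect_identical(rownames(relaxed), rownames(m))
  expect_error(plex_completeness_filter(m, plex[1:3]), "plex")
})

test_that("knn imputation matches a brute-force neighbor search", {
  set.seed(4)
  m <- named_matrix(rnorm(35), nrow = 7)
  m[3, 2] <- NA
  k <- 2
  out <- knn_impute(m, k = k)
  # oracle: rank all other features by mean squared difference over
  # co-observed samples, take the k nearest observed at the NA position
  d <- sapply(seq_len(7), function(j) {
    if (j == 3) return(Inf)
    shared <- !is.na(m[3, ]) & !is.na(m[j, ])
    sqrt(mean((m[3, shared] - m[j, shared])^2))
  })
  nb <- order(d)[1:k]
  expect_equal(out[3, 2], mean(m[nb, 2]))
  # observed entries untouched, no NA remains
  expect_identical(out[-3, ], m[-3, ])
  expect_false(anyNA(out))
})

test_that("knn imputation copies an identical neighbor and is identity without NA", {
  m <- named_matrix(c(1, 1, 5, 2, 2, 6, 3, 3, 7, 4, NA, 8), nrow = 3)
  out <- knn_impute(m, k = 1)
  expect_equal(out[2, 4], 4)   # f2 identical to f1 where observed
  full <- named_matrix(rnorm(20), nrow = 4)
  expect_identical(knn_impute(full), full)
  expect_error(knn_impute(named_matrix(NA_real_, nrow = 1)), "observed")
})

test_that("EB correction with shrink = 0 equals per-feature OLS residualization", {
  set.seed(5)
  n <- 30
  ann <- data.frame(loading_mass = runif(n, 30, 70),
                    plex = factor(rep(1:3, each = 10)),
                    row.names = paste0("s", 1:n))
  m <- named_matrix(rnorm(8 * n), nrow = 8)
  out <- eb_covariate_correction(m, ann, shrink = 0)
  for (i in 1:8) {
    fit <- stats::lm(m[i, ] ~ ann$loading_mass + ann$plex)
    expect_equal(unname(out[i, ] - mean(out[i, ])),
                 unname(stats::residuals(fit)), tolerance = 1e-8)
  }
  # feature means preserved
  expect_equal(rowMeans(out), rowMeans(m), tolerance = 1e-10)
})

test_that("EB correction with shrink = 0 on one categorical equals per-level centering", {
  set.seed(6)
  grp <- factor(rep(c("a", "b"), each = 8))
  ann <- data.frame(batch = grp, row.names = paste0("s", 1:16))
  m <- named_matrix(rnorm(48), nrow = 3)
  out <- eb_covariate_correction(m, ann, covariates = "batch", shrink = 0)
  manual <- t(apply(m, 1, function(y)
    y - stats::ave(y, grp) + mean(y)))     # per-level centered, mean restored
  expect_equal(unname(out), unname(manual), tolerance = 1e-10)
})

test_that("EB correction removes a planted loading-mass slope", {
  set.seed(7)
  n <- 40
  mass <- runif(n, 30, 70)
  ann <- data.frame(loading_mass = mass, row.names = paste0("s", 1:n))
  m <- named_matrix(rep(2 * mass, each = 5), nrow = 5)
  out <- eb_covariate_correction(m, ann, covariates = "loading_mass")
  # the planted slope is removed entirely: what remains is flat
  for (i in 1:5) {
    expect_lt(abs(stats::coef(stats::lm(out[i, ] ~ mass))[2]), 1e-8)
    expect_lt(stats::sd(out[i, ]), 1e-8)
  }
})

test_that("EB shrinkage pulls coefficients toward the across-feature mean", {
  set.seed(8)
  n <- 60
  mass <- runif(n, 30, 70)
  ann <- data.frame(loading_mass = mass, row.names = paste0("s", 1:n))
  slopes <- c(rep(0.5, 10), 0.9)      # one outlier slope, high noise
  m <- named_matrix(outer(slopes, mass - mean(mass)) +
                      rnorm(11 * n, 0, 3), nrow = 11)
  ols <- eb_covariate_correction(m, ann, covariates = "loading_mass",
                                 shrink = 0)
  eb <- eb_covariate_correction(m, ann, covariates = "loading_mass")
  # implied corrected slopes: EB residual slope sits between OLS (0) and raw
  raw_slope <- apply(m, 1, function(y) stats::coef(stats::lm(y ~ mass))[2])
  eb_slope <- apply(eb, 1, function(y) stats::coef(stats::lm(y ~ mass))[2])
  ols_slope <- apply(ols, 1, function(y) stats::coef(stats::lm(y ~ mass))[2])
  expect_lt(max(abs(ols_slope)), 1e-10)
  expect_true(all(abs(eb_slope) <= abs(raw_slope - mean(raw_slope)) + 1e-6))
  # constant covariate dropped with warning
  ann$flat <- 1
  expect_warning(eb_covariate_correction(m, ann,
                                         covariates = c("loading_mass",
                                                        "flat")),
                 "constant")
})

test_that("covariate scan flags exact linear dependence and stays calibrated under the null", {
  set.seed(9)
  n <- 50
  mass <- runif(n, 30, 70)
  ann <- data.frame(loading_mass = mass,
                    plex = factor(rep(1:2, length.out = n)),
                    row.names = paste0("s", 1:n))
  m <- rbind(named_matrix(3 * mass + rnorm(n, 0, 1e-6), nrow = 1),
             named_matrix(rnorm(2 * n), nrow = 2, feature_prefix = "null"))
  rownames(m) <- c("lin", "null1", "null2")
  colnames(m) <- paste0("s", 1:n)
  scan <- covariate_effect_scan(m, ann, "loading_mass")
  expect_lt(scan$p["lin"], 1e-20)

  null_m <- named_matrix(rnorm(1000 * n), nrow = 1000)
  colnames(null_m) <- paste0("s", 1:n)
  null_scan <- covariate_effect_scan(null_m, ann, "loading_mass")
  expect_lte(null_scan$significant_fraction, 0.07)
  cat_scan <- covariate_effect_scan(null_m, ann, "plex")
  expect_lte(cat_scan$significant_fraction, 0.07)
  ann$flat <- 1
  expect_error(covariate_effect_scan(null_m, ann, "flat"), "constant")
})

test_that("global sample-median correction factors transfer to the phosphoproteome", {
  set.seed(10)
  offs <- rnorm(6)
  g <- named_matrix(rnorm(60), nrow = 10) + rep(offs, each = 10)
  ph <- named_matrix(rnorm(30), nrow = 5) + rep(offs, each = 5)
  ctr <- sample_median_centering(g)
  expect_lt(max(abs(apply(ctr$matrix, 2, stats::median))), 1e-12)
  ph_c <- apply_sample_correction(ph, ctr$factors)
  expect_equal(unname(ph_c), unname(ph - rep(ctr$factors, each = 5)))
})
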