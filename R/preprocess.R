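#' Reporter-ion relative abundance
#'
#' Converts TMT reporter-ion intensities to log2 relative abundance: the ratio
#' of each sample channel to the reference channel, log2 transformed and
#' zero-centered across samples for each feature. Features whose reference
#' intensity is missing, zero or negative are flagged all-NA; zero sample
#' intensities become NA (no signal).
#'
#' @param intensities features x channels nonnegative intensity matrix,
#'   including the reference channel column.
#' @param reference_channel column name of the reference channel.
#' @return features x samples log2 relative abundance matrix (reference
#'   column removed), each row zero-mean over its observed entries.
#' @export
#' @examples
#' x <- matrix(c(4, 1, 2), 1, dimnames = list("f1", c("s1", "s2", "ref")))
#' relative_abundance(x, "ref")
relative_abundance <- function(intensities, reference_channel) {
  assert_matrix(intensities, "intensity table")
  if (!reference_channel %in% colnames(intensities))
    stop("reference channel '", reference_channel, "' not found", call. = FALSE)
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be nonnegative", call. = FALSE)
  ref <- intensities[, reference_channel]
  m <- intensities[, setdiff(colnames(intensities), reference_channel),
                   drop = FALSE]
  m[m == 0] <- NA
  out <- log2(sweep(m, 1L, ref, `/`))
  out[is.na(ref) | ref <= 0, ] <- NA
  out - rowMeans(out, na.rm = TRUE)
}

#' Filter features by missing fraction
#'
#' Retains features present in at least `1 - max_missing_frac` of the samples
#' (missing fraction strictly greater than the threshold removes the
#' feature); order and values of retained rows are untouched.
#'
#' @param m feature x sample matrix (NA = missing).
#' @param max_missing_frac maximum tolerated missing fraction (default 0.5,
#'   the "present in at least 50% of the samples" rule, boundary inclusive).
#' @return row subset of `m`.
#' @export
filter_missingness <- function(m, max_missing_frac = 0.5) {
  assert_matrix(m)
  m[rowMeans(is.na(m)) <= max_missing_frac, , drop = FALSE]
}

#' Median polish residuals
#'
#' Tukey's median polish: alternately sweeps out row and column medians until
#' the largest change falls below `tol`, returning the residual matrix. NA
#' entries are ignored in the medians and stay NA. `method = "center"`
#' performs a single row- then column-median centering pass instead of the
#' full alternating polish.
#'
#' @param m feature x sample matrix.
#' @param max_iter maximum polish iterations (warning if not converged).
#' @param tol convergence tolerance on the change in total absolute residual.
#' @param method `"polish"` (full Tukey polish, default) or `"center"`.
#' @return residual matrix, same dimensions and dimnames as `m`.
#' @export
median_polish <- function(m, max_iter = 10L, tol = 0.01,
                          method = c("polish", "center")) {
  assert_matrix(m)
  method <- match.arg(method)
  if (any(rowSums(!is.na(m)) == 0) || any(colSums(!is.na(m)) == 0))
    stop("all-NA rows/columns are not polishable", call. = FALSE)
  if (method == "center") {
    out <- m - apply(m, 1L, stats::median, na.rm = TRUE)
    return(sweep(out, 2L, apply(out, 2L, stats::median, na.rm = TRUE)))
  }
  fit <- stats::medpolish(m, eps = tol, maxiter = max_iter,
                          trace.iter = FALSE, na.rm = TRUE)
  res <- fit$residuals
  dimnames(res) <- dimnames(m)
  res
}

resolve_plex <- function(m, plex) {
  if (is.data.frame(plex)) {
    if (!all(colnames(m) %in% rownames(plex)))
      stop("unknown plex assignment for sample(s): ",
           paste(setdiff(colnames(m), rownames(plex)), collapse = ", "),
           call. = FALSE)
    plex <- plex[colnames(m), "plex"]
  }
  if (length(plex) != ncol(m))
    stop("plex must give one plex per sample", call. = FALSE)
  if (anyNA(plex)) stop("unknown plex for some samples", call. = FALSE)
  factor(plex)
}

#' Filter features by plex completeness
#'
#' A plex is "missing" for a feature when every sample of that plex is NA.
#' Retains features missing in at most `max_missing_plexes` plexes;
#' `max_missing_plexes = 0` is the strict rule (at least one measurement in
#' every plex).
#'
#' @param m feature x sample matrix.
#' @param plex plex per sample (vector aligned with columns, or an annotation
#'   data.frame with a `plex` column and sample rownames).
#' @param max_missing_plexes maximum number of fully missing plexes.
#' @return row subset of `m`.
#' @export
plex_completeness_filter <- function(m, plex, max_missing_plexes = 0L) {
  assert_matrix(m)
  plex <- resolve_plex(m, plex)
  obs <- !is.na(m)
  seen <- sapply(levels(plex), function(p)
    rowSums(obs[, plex == p, drop = FALSE]) > 0)
  m[rowSums(!seen) <= max_missing_plexes, , drop = FALSE]
}

#' K-nearest-neighbor imputation in feature space
#'
#' Replaces each missing value with the mean, at that sample, of the k
#' nearest feature rows by Euclidean distance computed over co-observed
#' samples (root mean squared difference, so features co-observed on
#' different sample counts are comparable). Features with no eligible
#' neighbor at a sample fall back to their own observed row mean. Observed
#' entries are never modified.
#'
#' @param m feature x sample matrix (every feature needs >= 1 observed value).
#' @param k number of neighbors.
#' @return matrix with no NA.
#' @export
knn_impute <- function(m, k = 10L) {
  assert_matrix(m)
  if (nrow(m) == 0 || ncol(m) == 0) stop("empty matrix", call. = FALSE)
  if (!anyNA(m)) return(m)
  if (any(rowSums(!is.na(m)) == 0))
    stop("feature(s) with no observed value cannot be imputed", call. = FALSE)

  obs <- !is.na(m)
  Z <- m; Z[!obs] <- 0
  Mo <- obs * 1
  co <- tcrossprod(Mo)                       # co-observation counts
  ss <- tcrossprod(Z^2, Mo) + tcrossprod(Mo, Z^2) - 2 * tcrossprod(Z)
  D <- sqrt(pmax(ss, 0) / pmax(co, 1))
  D[co == 0] <- Inf
  diag(D) <- Inf

  out <- m
  row_means <- rowMeans(m, na.rm = TRUE)
  for (i in which(rowSums(!obs) > 0)) {
    ord <- order(D[i, ])
    ord <- ord[is.finite(D[i, ord])]
    for (j in which(!obs[i, ])) {
      nb <- ord[obs[ord, j]]
      out[i, j] <- if (length(nb)) mean(m[nb[seq_len(min(k, length(nb)))], j])
                   else row_means[i]
    }
  }
  out
}

build_covariate_design <- function(ann, covariates, n) {
  cols <- list()
  for (cv in covariates) {
    v <- ann[[cv]]
    if (is.null(v)) stop("covariate '", cv, "' not in annotation", call. = FALSE)
    if (anyNA(v)) stop("covariate '", cv, "' has missing values", call. = FALSE)
    if (is.numeric(v)) {
      if (stats::sd(v) == 0) {
        warning("constant covariate '", cv, "' dropped")
        next
      }
      cols[[cv]] <- matrix((v - mean(v)) / stats::sd(v),
                           dimnames = list(NULL, cv))
    } else {
      v <- droplevels(as.factor(v))
      if (nlevels(v) < 2) {
        warning("constant covariate '", cv, "' dropped")
        next
      }
      d <- stats::model.matrix(~v)[, -1, drop = FALSE]
      colnames(d) <- paste0(cv, levels(v)[-1])
      cols[[cv]] <- scale(d, center = TRUE, scale = FALSE)
    }
  }
  if (!length(cols)) return(NULL)
  D <- do.call(cbind, cols)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    warning("collinear covariate column(s) dropped")
    D <- D[, qrD$pivot[seq_len(qrD$rank)], drop = FALSE]
  }
  D
}

#' Empirical-Bayes covariate correction
#'
#' Removes loading-mass and plex (or any supplied) covariate effects from an
#' abundance matrix. Per feature, a linear model is fit on the standardized
#' continuous and mean-centered one-hot categorical covariates; the
#' per-feature coefficients are then shrunk toward their across-feature mean
#' with an empirical-Bayes weight estimated by method of moments
#' (prior variance = coefficient dispersion in excess of average sampling
#' variance), and the shrunken fitted covariate effects are subtracted.
#' Because the design columns are centered, feature means are preserved
#' exactly.
#'
#' @param m feature x sample matrix, imputed (no NA).
#' @param ann annotation data.frame (sample rownames matching columns of `m`).
#' @param covariates annotation columns to correct for.
#' @param shrink optional fixed shrinkage intensity in [0, 1] overriding the
#'   empirical-Bayes weights: 0 = ordinary per-feature least-squares
#'   residualization, 1 = every feature corrected by the across-feature mean
#'   coefficient. `NULL` (default) uses the EB weights.
#' @return corrected matrix, same dimensions as `m`.
#' @export
eb_covariate_correction <- function(m, ann,
                                    covariates = c("loading_mass", "plex"),
                                    shrink = NULL) {
  assert_matrix(m)
  if (anyNA(m)) stop("impute the matrix before correction", call. = FALSE)
  if (!all(colnames(m) %in% rownames(ann)))
    stop("annotation missing for some samples", call. = FALSE)
  ann <- ann[colnames(m), , drop = FALSE]
  D <- build_covariate_design(ann, covariates, ncol(m))
  if (is.null(D)) return(m)

  n <- ncol(m); p <- ncol(D)
  DtD_inv <- solve(crossprod(D))
  # B: p x F coefficient matrix from per-feature OLS (common design)
  Xc <- m - rowMeans(m)
  B <- DtD_inv %*% crossprod(D, t(Xc))
  resid <- Xc - t(D %*% B)
  df <- n - p - 1
  sigma2 <- rowSums(resid^2) / max(df, 1)

  B_shrunk <- B
  for (j in seq_len(p)) {
    b <- B[j, ]
    se2 <- sigma2 * DtD_inv[j, j]
    mu_j <- mean(b)
    if (is.null(shrink)) {
      tau2 <- max(stats::var(b) - mean(se2), 0)
      w <- tau2 / (tau2 + se2)           # weight on the per-feature estimate
    } else {
      w <- 1 - shrink
    }
    B_shrunk[j, ] <- w * b + (1 - w) * mu_j
  }
  m - t(D %*% B_shrunk)
}

#' Scan features for a covariate effect
#'
#' Per-feature association test against a single covariate: a regression
#' t-test for continuous covariates (pairwise-complete), a one-way ANOVA F
#' test for categorical ones. P-values are Benjamini-Hochberg adjusted across
#' features and the fraction significant at `alpha` is reported — the
#' diagnostic used to decide whether a technical covariate (loading mass,
#' plex) needs correction.
#'
#' @param m feature x sample matrix (NA tolerated pairwise).
#' @param ann annotation data.frame with sample rownames.
#' @param covariate annotation column name.
#' @param alpha significance level on the adjusted p-values.
#' @return list with `p`, `p_adjusted` (per feature) and
#'   `significant_fraction`.
#' @export
covariate_effect_scan <- function(m, ann, covariate, alpha = 0.05) {
  assert_matrix(m)
  if (ncol(m) < 3) stop("need >= 3 samples", call. = FALSE)
  ann <- ann[colnames(m), , drop = FALSE]
  v <- ann[[covariate]]
  if (is.null(v)) stop("covariate '", covariate, "' not found", call. = FALSE)
  if (is.numeric(v)) {
    if (stats::sd(v) == 0) stop("constant covariate", call. = FALSE)
    r <- suppressWarnings(
      stats::cor(v, t(m), use = "pairwise.complete.obs"))[1, ]
    n_obs <- rowSums(!is.na(m) & rep(!is.na(v), each = nrow(m)))
    df <- pmax(n_obs - 2, 1)
    tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df)
    p[is.na(r)] <- NA
  } else {
    g <- droplevels(as.factor(v))
    if (nlevels(g) < 2) stop("constant covariate", call. = FALSE)
    p <- apply(m, 1L, function(y) {
      keep <- !is.na(y)
      gi <- droplevels(g[keep])
      if (nlevels(gi) < 2 || sum(keep) <= nlevels(gi)) return(NA_real_)
      stats::anova(stats::lm(y[keep] ~ gi))[["Pr(>F)"]][1]
    })
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p = p, p_adjusted = p_adj,
       significant_fraction = mean(p_adj < alpha, na.rm = TRUE))
}

#' Per-sample median centering factors
#'
#' Computes each sample's median abundance in `m` and subtracts it, returning
#' the centered matrix and the factors so the same correction can be applied
#' to a paired dataset — the phosphoproteome is loading-normalized with the
#' factors derived from the global proteome.
#'
#' @param m feature x sample matrix.
#' @return list with `matrix` (centered) and `factors` (per-sample medians).
#' @export
sample_median_centering <- function(m) {
  assert_matrix(m)
  f <- apply(m, 2L, stats::median, na.rm = TRUE)
  list(matrix = sweep(m, 2L, f), factors = f)
}

#' Apply global-proteome sample correction factors to another matrix
#'
#' @param m matrix to correct (e.g. phosphoproteome), columns matching
#'   `factors` names.
#' @param factors per-sample offsets, typically
#'   `sample_median_centering(global)$factors`.
#' @return corrected matrix.
#' @export
apply_sample_correction <- function(m, factors) {
  assert_matrix(m)
  if (!all(colnames(m) %in% names(factors)))
    stop("correction factors missing for some samples", call. = FALSE)
  sweep(m, 2L, factors[colnames(m)])
}
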