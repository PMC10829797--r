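#' Standardize features and split signed values for NMF
#'
#' z-scores every feature (mean 0, sd 1) within its modality, then splits each
#' feature row into a nonnegative pair: a positive part `max(x, 0)` and a
#' negative part `max(-x, 0)`. Stacking the modalities row-wise yields the
#' nonnegative matrix (twice as many rows as input features) that NMF
#' factorizes. The original z-scored value is recovered as pos - neg.
#'
#' @param matrices named list of feature x sample matrices (no NA; impute
#'   first). Sample sets are intersected and aligned.
#' @return `signed_split` list with `X` (nonnegative 2F x S matrix) and
#'   `provenance` (data.frame: feature, modality, sign per row of X).
#' @export
standardize_and_split <- function(matrices) {
  if (is.matrix(matrices)) matrices <- list(data = matrices)
  shared <- Reduce(intersect, lapply(matrices, colnames))
  if (!length(shared)) stop("no shared samples across modalities", call. = FALSE)
  blocks <- list(); prov <- list()
  for (mod in names(matrices)) {
    m <- matrices[[mod]][, shared, drop = FALSE]
    if (anyNA(m))
      stop("matrices must be imputed (no NA) before splitting", call. = FALSE)
    sds <- apply(m, 1L, stats::sd)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " zero-variance feature(s) dropped in ", mod)
      m <- m[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    z <- (m - rowMeans(m)) / sds
    blocks[[mod]] <- rbind(pmax(z, 0), pmax(-z, 0))
    prov[[mod]] <- data.frame(feature = rep(rownames(m), 2),
                              modality = mod,
                              sign = rep(c("pos", "neg"), each = nrow(m)))
  }
  X <- do.call(rbind, blocks)
  prov <- do.call(rbind, prov)
  rownames(X) <- paste(prov$modality, prov$feature, prov$sign, sep = "|")
  rownames(prov) <- NULL
  structure(list(X = X, provenance = prov), class = "signed_split")
}

as_nmf_input <- function(X) {
  if (inherits(X, "signed_split")) X <- X$X
  if (any(X < 0)) stop("NMF input must be nonnegative", call. = FALSE)
  X
}

kl_divergence <- function(X, WH) {
  pos <- X > 0
  sum(X[pos] * log(X[pos] / WH[pos])) - sum(X) + sum(WH)
}

#' Non-negative matrix factorization by multiplicative KL updates
#'
#' Approximates a nonnegative matrix X as W H (W: rows x k "metagenes",
#' H: k x samples memberships) by minimizing the generalized Kullback-Leibler
#' divergence with the classic multiplicative update rules, from uniform
#' random initialization scaled to the data mean. The objective is
#' non-increasing under the updates; iteration stops when the relative
#' objective change falls below `tol` or at `max_iter`.
#'
#' @param X nonnegative matrix or a `signed_split`.
#' @param k factorization rank (0 < k < min(dim(X))).
#' @param seed integer seed for the random initialization.
#' @param max_iter maximum iterations.
#' @param tol relative objective-change convergence threshold (checked every
#'   10 iterations, every iteration when `track_objective`).
#' @param track_objective record the objective at every iteration (slower;
#'   used to assert monotonicity).
#' @return `nmf_fit` list: `W`, `H`, `objective`, `n_iter`, `seed`,
#'   `objective_trace` (when tracked).
#' @export
nmf_factorize <- function(X, k, seed = 1, max_iter = 2000, tol = 1e-6,
                          track_objective = FALSE) {
  X <- as_nmf_input(X)
  if (k <= 0 || k >= min(dim(X)))
    stop("k must satisfy 0 < k < min(dim(X))", call. = FALSE)
  set.seed(as.integer(seed))
  scale0 <- sqrt(mean(X) / k)
  W0 <- matrix(stats::runif(nrow(X) * k), nrow(X), k) * scale0
  H0 <- matrix(stats::runif(k * ncol(X)), k, ncol(X)) * scale0
  fit <- .nmf_mu_kl(X, W0, H0, as.integer(max_iter), tol, track_objective)
  W <- fit$W; H <- fit$H
  dimnames(W) <- list(rownames(X), paste0("metagene", seq_len(k)))
  dimnames(H) <- list(paste0("metagene", seq_len(k)), colnames(X))
  structure(list(W = W, H = H, objective = fit$objective,
                 n_iter = fit$n_iter, seed = as.integer(seed), k = k,
                 objective_trace = if (track_objective) fit$objective_trace),
            class = "nmf_fit")
}

#' Assign samples to clusters from an NMF factorization
#'
#' Each sample goes to the metagene (row of H) with the maximum membership in
#' its column; ties break to the lowest row index.
#'
#' @param fit an `nmf_fit`.
#' @return integer cluster label per sample (named).
#' @export
assign_clusters <- function(fit) {
  H <- fit$H
  if (any(colSums(H) == 0))
    stop("sample(s) with all-zero membership column cannot be assigned",
         call. = FALSE)
  stats::setNames(apply(H, 2L, which.max), colnames(H))
}

#' Consensus clustering over NMF restarts
#'
#' Runs NMF `n_runs` times from different random initializations
#' (seeds = `seed + run - 1`), records each run's cluster labels and averages
#' the sample co-membership indicators into the consensus (average adjacency)
#' matrix A. Final labels come from average-linkage hierarchical clustering of
#' 1 - A cut at k.
#'
#' @param X nonnegative matrix or `signed_split`.
#' @param k number of clusters.
#' @param n_runs number of NMF restarts.
#' @param seed base seed.
#' @param max_iter,tol per-run NMF settings (consensus runs default to a
#'   lighter convergence than a single deep factorization).
#' @return `consensus_result` list: `k`, `A` (samples x samples in [0,1],
#'   symmetric, unit diagonal), `labels`, `cophenetic_corr`, `n_runs`,
#'   `run_labels` (runs x samples matrix).
#' @export
consensus_cluster <- function(X, k, n_runs = 50, seed = 1,
                              max_iter = 200, tol = 1e-4) {
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  X <- as_nmf_input(X)
  n <- ncol(X)
  A <- matrix(0, n, n, dimnames = list(colnames(X), colnames(X)))
  run_labels <- matrix(NA_integer_, n_runs, n,
                       dimnames = list(NULL, colnames(X)))
  ok <- 0L
  for (r in seq_len(n_runs)) {
    lab <- tryCatch({
      fit <- nmf_factorize(X, k, seed = seed + r - 1L,
                           max_iter = max_iter, tol = tol)
      assign_clusters(fit)
    }, error = function(e) {
      warning("NMF run ", r, " failed and was excluded: ",
              conditionMessage(e))
      NULL
    })
    if (is.null(lab)) next
    A <- A + outer(lab, lab, `==`)
    run_labels[r, ] <- lab
    ok <- ok + 1L
  }
  if (ok == 0L) stop("all NMF runs failed", call. = FALSE)
  A <- A / ok
  labels <- stats::cutree(stats::hclust(stats::as.dist(1 - A),
                                        method = "average"), k = k)
  res <- structure(list(k = k, A = A, labels = labels, n_runs = ok,
                        run_labels = run_labels[!is.na(run_labels[, 1]), ,
                                                drop = FALSE]),
                   class = "consensus_result")
  res$cophenetic_corr <- cophenetic_correlation(res)
  res
}

#' Cophenetic correlation of a consensus matrix
#'
#' Pearson correlation between the off-diagonal consensus distances (1 - A)
#' and the cophenetic (ultrametric) distances of their average-linkage
#' dendrogram; near 1 means the consensus matrix is well explained by a clean
#' hierarchical split, the statistic used to choose the cluster number.
#'
#' @param x a `consensus_result` or a symmetric consensus matrix A.
#' @return correlation in [-1, 1]; NA when A is constant.
#' @export
cophenetic_correlation <- function(x) {
  A <- if (inherits(x, "consensus_result")) x$A else x
  d <- stats::as.dist(1 - A)
  if (stats::sd(d) == 0) return(NA_real_)
  coph <- stats::cophenetic(stats::hclust(d, method = "average"))
  if (stats::sd(coph) == 0) return(NA_real_)
  stats::cor(d, coph)
}

#' Select the number of clusters by cophenetic correlation
#'
#' Runs consensus clustering for every k in `k_range` and returns the k with
#' the highest cophenetic correlation (ties break to the smaller k), together
#' with the full model-selection curve.
#'
#' @param X nonnegative matrix or `signed_split`.
#' @param k_range candidate cluster numbers.
#' @param n_runs NMF restarts per k.
#' @param seed base seed (shared across k so runs differ only by rank).
#' @param ... passed to [consensus_cluster()].
#' @return list with `k_best`, `curve` (data.frame k, cophenetic) and
#'   `results` (per-k `consensus_result`s, named by k).
#' @export
select_k <- function(X, k_range = 2:8, n_runs = 50, seed = 1, ...) {
  results <- lapply(k_range, function(k)
    consensus_cluster(X, k, n_runs = n_runs, seed = seed, ...))
  names(results) <- k_range
  curve <- data.frame(k = k_range,
                      cophenetic = vapply(results, function(r)
                        r$cophenetic_corr, numeric(1)))
  k_best <- curve$k[which.max(curve$cophenetic)]
  list(k_best = k_best, curve = curve, results = results)
}
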