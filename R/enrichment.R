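#' Per-subtype ranked score vector
#'
#' Mean-centers every feature across the cohort, then averages the centered
#' values over the samples of one subtype; the resulting named score vector
#' (sorted descending) is the input to preranked GSEA and KSEA.
#'
#' @param m feature x sample matrix (NA tolerated).
#' @param labels subtype per sample.
#' @param subtype the subtype whose scores to compute.
#' @return named numeric vector, sorted descending.
#' @export
subtype_rank_vector <- function(m, labels, subtype) {
  assert_matrix(m)
  sel <- labels == subtype
  if (!any(sel)) stop("subtype has no samples", call. = FALSE)
  centered <- m - rowMeans(m, na.rm = TRUE)
  scores <- rowMeans(centered[, sel, drop = FALSE], na.rm = TRUE)
  sort(scores[is.finite(scores)], decreasing = TRUE)
}

# Weighted Kolmogorov-Smirnov enrichment score for hit positions in a ranked
# list: hits increment the running sum by |score|^weight (normalized), misses
# decrement by 1/(N - Nh); ES is the maximum deviation from zero.
gsea_es <- function(ranked_abs_w, hit_idx, n) {
  m <- length(hit_idx)
  hit_idx <- sort(hit_idx)
  w <- ranked_abs_w[hit_idx]
  nr <- sum(w)
  if (nr == 0) { w <- rep(1, m); nr <- m }   # all-zero scores: unweighted
  miss_step <- 1 / (n - m)
  cum_hit <- cumsum(w) / nr
  # running sum just after each hit, and just before each hit
  after <- cum_hit - (hit_idx - seq_len(m)) * miss_step
  before <- c(0, cum_hit[-m]) - (hit_idx - seq_len(m)) * miss_step
  lo <- min(before)
  hi <- max(after)
  if (hi >= -lo) hi else lo
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov enrichment scores over a ranked feature list:
#' walking down the ranking, set members increment the running sum
#' proportionally to |score|^weight (normalized to the set total) and
#' non-members decrement it by 1/(N - set size); ES is the maximum deviation.
#' Significance comes from feature-label (gene-set) permutation: `n_perm`
#' random same-size sets give each set's null, the two-sided p is the
#' fraction of null |ES| at least as large, and NES divides ES by the mean
#' |null ES| of the same sign. P-values are BH-adjusted across sets.
#'
#' @param scores named score vector (need not be pre-sorted).
#' @param sets named list of feature-id vectors.
#' @param n_perm number of random-set permutations.
#' @param weight score weighting exponent (1 = classic weighted statistic).
#' @param min_size,max_size set-size bounds after intersecting with the
#'   ranked ids; sets outside the bounds are skipped with a note.
#' @param seed integer seed for the permutations.
#' @return data.frame with `set`, `size`, `ES`, `NES`, `p`, `fdr`, sorted by
#'   p; attribute `skipped` lists sets outside the size bounds.
#' @export
gsea_preranked <- function(scores, sets, n_perm = 1000, weight = 1,
                           min_size = 5, max_size = 500, seed = 1) {
  scores <- sort(scores, decreasing = TRUE)
  n <- length(scores)
  ids <- names(scores)
  set.seed(as.integer(seed))
  idx_of <- stats::setNames(seq_len(n), ids)
  sizes <- integer(0)
  keep <- list()
  skipped <- character(0)
  for (nm in names(sets)) {
    members <- intersect(sets[[nm]], ids)
    if (length(members) < min_size || length(members) > max_size) {
      skipped <- c(skipped, nm)
      next
    }
    keep[[nm]] <- idx_of[members]
    sizes <- c(sizes, length(members))
  }
  if (length(skipped))
    message(length(skipped), " set(s) outside size bounds skipped")
  if (!length(keep))
    return(structure(data.frame(set = character(), size = integer(),
                                ES = numeric(), NES = numeric(),
                                p = numeric(), fdr = numeric()),
                     skipped = skipped))
  w_abs <- abs(scores)^weight
  # one shared null per distinct set size
  nulls <- lapply(unique(sizes), function(m)
    vapply(seq_len(n_perm), function(b)
      gsea_es(w_abs, sample.int(n, m), n), numeric(1)))
  names(nulls) <- as.character(unique(sizes))

  res <- do.call(rbind, lapply(names(keep), function(nm) {
    hit <- keep[[nm]]
    es <- gsea_es(w_abs, hit, n)
    null <- nulls[[as.character(length(hit))]]
    p <- (1 + sum(abs(null) >= abs(es))) / (n_perm + 1)
    same <- null[sign(null) == sign(es)]
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    data.frame(set = nm, size = length(hit), ES = es, NES = nes, p = p)
  }))
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p), ]
  rownames(res) <- NULL
  structure(res, skipped = skipped)
}

#' Kinase-substrate enrichment analysis
#'
#' For each kinase, compares the mean score of its quantified substrate
#' phosphosites to the background of all quantified sites:
#' `z = (mean(substrates) - mean(all)) * sqrt(m) / sd(all)` with m the
#' substrate count, two-sided normal p, BH adjustment across kinases.
#'
#' @param scores named phosphosite score vector (all quantified sites; the
#'   background population).
#' @param map data.frame with columns `kinase` and `substrate` (site ids).
#' @return data.frame with `kinase`, `m`, `z`, `p`, `fdr`; kinases with no
#'   quantified substrate are omitted. `z` is NA when the background sd is 0.
#' @export
ksea <- function(scores, map) {
  if (!all(c("kinase", "substrate") %in% colnames(map)))
    stop("map needs 'kinase' and 'substrate' columns", call. = FALSE)
  mp <- mean(scores)
  delta <- stats::sd(scores)
  kinases <- unique(map$kinase)
  res <- do.call(rbind, lapply(kinases, function(kin) {
    subs <- intersect(map$substrate[map$kinase == kin], names(scores))
    if (!length(subs)) return(NULL)
    m <- length(subs)
    z <- if (delta == 0) NA_real_
         else (mean(scores[subs]) - mp) * sqrt(m) / delta
    data.frame(kinase = kin, m = m, z = z,
               p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)))
  }))
  if (is.null(res)) stop("no kinase has a quantified substrate", call. = FALSE)
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}
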