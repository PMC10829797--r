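#' Filter drugs by testing breadth and sensitivity count
#'
#' Keeps drugs assayed on at least `min_tested` samples that also have at
#' least `min_sensitive` sensitive samples, a sensitive sample being one
#' with AUC strictly below `sens_threshold` (the ex vivo screening criterion:
#' >= 100 tested, >= 10 with AUC < 100). Values of retained columns are
#' untouched.
#'
#' @param tab samples x drugs AUC matrix (NA = not assayed).
#' @param min_tested minimum number of assayed samples.
#' @param min_sensitive minimum number of sensitive samples.
#' @param sens_threshold AUC below which a sample counts as sensitive
#'   (strict inequality).
#' @return column subset of `tab`.
#' @export
filter_drugs <- function(tab, min_tested = 100, min_sensitive = 10,
                         sens_threshold = 100) {
  assert_matrix(tab, "drug table")
  tested <- colSums(!is.na(tab))
  sensitive <- colSums(tab < sens_threshold, na.rm = TRUE)
  tab[, tested >= min_tested & sensitive >= min_sensitive, drop = FALSE]
}

welch_row <- function(auc, in_group) {
  x <- auc[in_group & !is.na(auc)]
  y <- auc[!in_group & !is.na(auc)]
  if (length(x) < 2 || length(y) < 2)
    return(c(t = NA, p = NA, mean_in = mean(x), mean_out = mean(y),
             n_in = length(x), n_out = length(y)))
  tt <- tryCatch(stats::t.test(x, y),   # Welch by default
                 error = function(e) NULL)
  if (is.null(tt)) {                    # both groups constant
    equal <- isTRUE(all.equal(mean(x), mean(y)))
    return(c(t = if (equal) 0 else NA, p = if (equal) 1 else NA,
             mean_in = mean(x), mean_out = mean(y),
             n_in = length(x), n_out = length(y)))
  }
  c(t = unname(tt$statistic), p = tt$p.value,
    mean_in = mean(x), mean_out = mean(y),
    n_in = length(x), n_out = length(y))
}

#' Welch-test association of drug response with a grouping
#'
#' Per drug, Welch's unequal-variance t-test of AUC in the group of interest
#' versus the rest. A logical/binary grouping tests TRUE vs FALSE; a factor
#' with more than two levels is expanded into one-vs-rest contrasts per
#' level. The t sign convention is positive = group of interest more
#' resistant (higher AUC). BH adjustment spans the whole family of
#' (drug x group) tests; `significant` flags adjusted p < 0.05.
#'
#' @param tab samples x drugs AUC matrix.
#' @param grouping logical/binary vector, or factor, aligned with rows.
#' @return data.frame: drug, group, t, p, mean_in, mean_out, n_in, n_out,
#'   p_adjusted, significant.
#' @export
welch_association <- function(tab, grouping) {
  assert_matrix(tab, "drug table")
  if (length(grouping) != nrow(tab))
    stop("grouping must align with drug-table rows", call. = FALSE)
  if (is.logical(grouping) || all(grouping %in% c(0, 1))) {
    contrasts <- list(group = as.logical(grouping))
  } else {
    g <- as.factor(grouping)
    contrasts <- lapply(levels(g), function(l) g == l)
    names(contrasts) <- levels(g)
  }
  res <- do.call(rbind, lapply(names(contrasts), function(cn)
    do.call(rbind, lapply(colnames(tab), function(d) {
      stats_row <- welch_row(tab[, d], contrasts[[cn]])
      data.frame(drug = d, group = cn, t(stats_row))
    }))))
  res$p_adjusted <- stats::p.adjust(res$p, method = "BH")
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < 0.05
  rownames(res) <- NULL
  res
}

#' Fisher-exact enrichment of annotations in clusters
#'
#' Two-sided Fisher's exact test of each binary annotation (mutation or
#' clinical flag) against membership in each cluster, flagging p < 0.05.
#'
#' @param labels cluster label per sample.
#' @param annotation data.frame (or matrix) of binary/logical columns,
#'   one row per sample.
#' @return data.frame: cluster, annotation, odds_ratio, p, significant; NA
#'   when a margin is empty (constant annotation gives p = 1).
#' @export
fisher_enrichment <- function(labels, annotation) {
  annotation <- as.data.frame(annotation)
  if (nrow(annotation) != length(labels))
    stop("annotation must have one row per sample", call. = FALSE)
  clusters <- sort(unique(labels))
  res <- do.call(rbind, lapply(clusters, function(cl)
    do.call(rbind, lapply(colnames(annotation), function(a) {
      flag <- as.logical(annotation[[a]])
      ok <- !is.na(flag)
      tab <- table(factor(labels[ok] == cl, levels = c(TRUE, FALSE)),
                   factor(flag[ok], levels = c(TRUE, FALSE)))
      if (any(rowSums(tab) == 0)) {
        return(data.frame(cluster = cl, annotation = a,
                          odds_ratio = NA_real_, p = NA_real_))
      }
      ft <- stats::fisher.test(tab)
      data.frame(cluster = cl, annotation = a,
                 odds_ratio = unname(ft$estimate), p = ft$p.value)
    }))))
  res$significant <- !is.na(res$p) & res$p < 0.05
  rownames(res) <- NULL
  res
}

#' Within-subtype mutation effect on drug response
#'
#' Tests, per drug and per subtype, whether mutant and wild-type samples of
#' that subtype differ in AUC (Welch test), detecting subtype-restricted
#' mutation effects. BH adjustment spans the whole (drug x subtype) family;
#' `stars` annotates adjusted p by order of magnitude (* = 0.01, ** = 0.001).
#'
#' @param tab samples x drugs AUC matrix.
#' @param labels subtype per sample.
#' @param mutation binary mutation flag per sample.
#' @return data.frame: drug, subtype, t, p, mean_in (mutant), mean_out
#'   (wild-type), n_in, n_out, p_adjusted, significant, stars.
#' @export
interaction_analysis <- function(tab, labels, mutation) {
  assert_matrix(tab, "drug table")
  mutation <- as.logical(mutation)
  res <- do.call(rbind, lapply(sort(unique(labels)), function(st)
    do.call(rbind, lapply(colnames(tab), function(d) {
      sel <- labels == st
      stats_row <- welch_row(ifelse(sel, tab[, d], NA), mutation)
      data.frame(drug = d, subtype = st, t(stats_row))
    }))))
  res$p_adjusted <- stats::p.adjust(res$p, method = "BH")
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < 0.05
  res$stars <- significance_stars(res$p_adjusted)
  rownames(res) <- NULL
  res
}

#' Kaplan-Meier curves and log-rank test across subtypes
#'
#' Product-limit survival estimate per subtype and the k-group log-rank
#' chi-square test (k - 1 degrees of freedom) of survival differences.
#'
#' @param ann annotation data.frame with `survival_time` (>= 0) and
#'   `survival_event` (0/1) columns.
#' @param labels subtype per sample (aligned with rows of `ann`).
#' @return list with `fit` (a [survival::survfit] object), `chisq`, `df`
#'   and `p`.
#' @export
km_logrank <- function(ann, labels) {
  if (!all(c("survival_time", "survival_event") %in% colnames(ann)))
    stop("annotation needs survival_time and survival_event", call. = FALSE)
  if (any(ann$survival_time < 0, na.rm = TRUE))
    stop("negative survival times", call. = FALSE)
  keep <- !is.na(labels) & !is.na(ann$survival_time)
  d <- data.frame(time = ann$survival_time[keep],
                  event = ann$survival_event[keep],
                  group = factor(labels[keep]))
  d$group <- droplevels(d$group)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = d)
  if (nlevels(d$group) < 2)
    return(list(fit = fit, chisq = NA_real_, df = 0L, p = NA_real_))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd_$n) - 1
  list(fit = fit, chisq = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}
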