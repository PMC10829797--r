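#' Default drug specifications for synthetic cohorts
#'
#' Five ex vivo drug profiles covering the response archetypes the analysis
#' stratifies: a drug selectively sensitive in subtype 2 (venetoclax-like), one
#' sensitive in subtype 3, one driven by a FLT3 mutation regardless of subtype,
#' one whose mutation effect exists only within subtype 2 (a subtype x mutation
#' interaction, the sorafenib/FLT3-ITD analog), and a flat control. AUC values
#' live on the ex vivo dose-response scale [1, 300], lower = more sensitive.
#'
#' @param k number of subtypes the shifts refer to.
#' @return list of drug specification lists with fields `name`, `baseline`,
#'   `subtype_shift` (length-k), `mutation_shift` (named by gene),
#'   `interaction` (optional list with `gene`, `subtype`, `shift`),
#'   `noise_sd`, `fraction` (fraction of samples assayed).
#' @export
default_drug_specs <- function(k = 4) {
  shift <- function(at, by) { s <- numeric(k); s[at] <- by; s }
  list(
    list(name = "drug_s2",   baseline = 200, subtype_shift = shift(2, -110),
         mutation_shift = NULL, noise_sd = 15, fraction = 0.85),
    list(name = "drug_s3",   baseline = 200, subtype_shift = shift(3, -110),
         mutation_shift = NULL, noise_sd = 15, fraction = 0.85),
    list(name = "drug_flt3", baseline = 180, subtype_shift = numeric(k),
         mutation_shift = c(FLT3 = -70), noise_sd = 15, fraction = 0.75),
    list(name = "drug_ix",   baseline = 170, subtype_shift = numeric(k),
         mutation_shift = NULL,
         interaction = list(gene = "FLT3", subtype = 2, shift = -80),
         noise_sd = 15, fraction = 0.85),
    list(name = "drug_flat", baseline = 150, subtype_shift = numeric(k),
         mutation_shift = NULL, noise_sd = 15, fraction = 0.6)
  )
}

#' Configuration for a synthetic multiomic cohort
#'
#' Bundles and validates the parameters of [generate_cohort()]. Defaults are
#' the package's desk-scale study conditions: 160 samples carrying 4 planted
#' subtypes across three modalities, TMT-style plex batch offsets, a shared
#' positive loading-mass effect, mixed random and intensity-dependent
#' missingness, subtype-enriched mutations, subtype/mutation-driven drug AUCs
#' and subtype-dependent survival.
#'
#' @param n_samples number of samples.
#' @param k_true number of planted subtypes (>= 2).
#' @param n_features named counts of features per modality
#'   (`mrna`, `protein`, `phospho`).
#' @param subtype_effect_sd sd of planted per-feature subtype means
#'   (log2 abundance units).
#' @param noise_sd sd of i.i.d. measurement noise.
#' @param n_plexes number of TMT plexes (samples assigned round-robin).
#' @param plex_offset_sd sd of per-feature, per-plex batch offsets.
#' @param loading_mass_slope_mean,loading_mass_slope_sd mean and sd of the
#'   per-feature regression slope on loading mass (abundance units per ug).
#'   A positive mean models the shared direction of the effect: more peptide
#'   mass loaded raises measured abundance for essentially all features.
#' @param missing_rate missing-completely-at-random deletion probability.
#' @param mnar_strength extra missingness for low-abundance values (logistic
#'   in the value's z-score); 0 disables the intensity-dependent component.
#' @param mutation_rates genes x subtypes matrix of Bernoulli mutation rates
#'   (rownames = gene symbols).
#' @param drug_specs list of drug specifications, see [default_drug_specs()].
#' @param survival_hazards per-subtype hazard multipliers for exponential
#'   survival times.
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return validated `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 160,
                             k_true = 4,
                             n_features = c(mrna = 150, protein = 150,
                                            phospho = 100),
                             subtype_effect_sd = 1,
                             noise_sd = 1,
                             n_plexes = 8,
                             plex_offset_sd = 0.5,
                             loading_mass_slope_mean = 0.05,
                             loading_mass_slope_sd = 0.01,
                             missing_rate = 0.05,
                             mnar_strength = 0.3,
                             mutation_rates = NULL,
                             drug_specs = default_drug_specs(k_true),
                             survival_hazards = NULL,
                             seed = 1) {
  if (is.null(mutation_rates)) {
    mutation_rates <- rbind(
      FLT3 = c(0.15, 0.6, 0.15, 0.1),
      NPM1 = c(0.1, 0.45, 0.2, 0.1),
      TP53 = c(0.35, 0.05, 0.1, 0.1)
    )[, seq_len(min(4, k_true)), drop = FALSE]
    if (k_true > 4)
      mutation_rates <- mutation_rates[, rep_len(seq_len(4), k_true)]
  }
  if (is.null(survival_hazards))
    survival_hazards <- c(rep(1, k_true - 1), 0.4)
  cfg <- list(n_samples = n_samples, k_true = k_true,
              n_features = n_features,
              subtype_effect_sd = subtype_effect_sd, noise_sd = noise_sd,
              n_plexes = n_plexes, plex_offset_sd = plex_offset_sd,
              loading_mass_slope_mean = loading_mass_slope_mean,
              loading_mass_slope_sd = loading_mass_slope_sd,
              missing_rate = missing_rate, mnar_strength = mnar_strength,
              mutation_rates = mutation_rates, drug_specs = drug_specs,
              survival_hazards = survival_hazards, seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  stopifnot_cfg <- function(ok, msg)
    if (!ok) stop("invalid synthetic_config: ", msg, call. = FALSE)
  stopifnot_cfg(cfg$k_true >= 2, "k_true must be >= 2")
  stopifnot_cfg(cfg$n_samples >= 2 * cfg$k_true,
                "need at least 2 samples per planted subtype")
  stopifnot_cfg(all(cfg$n_features >= 1), "feature counts must be positive")
  stopifnot_cfg(all(c("mrna", "protein", "phospho") %in% names(cfg$n_features)),
                "n_features must name mrna, protein and phospho")
  stopifnot_cfg(cfg$missing_rate >= 0 && cfg$missing_rate <= 1,
                "missing_rate must be in [0,1]")
  stopifnot_cfg(cfg$mnar_strength >= 0, "mnar_strength must be >= 0")
  stopifnot_cfg(cfg$n_plexes >= 1, "n_plexes must be >= 1")
  stopifnot_cfg(all(cfg$mutation_rates >= 0 & cfg$mutation_rates <= 1),
                "mutation rates must be in [0,1]")
  stopifnot_cfg(ncol(cfg$mutation_rates) == cfg$k_true,
                "mutation_rates needs one column per subtype")
  stopifnot_cfg(length(cfg$survival_hazards) == cfg$k_true &&
                  all(cfg$survival_hazards > 0),
                "survival_hazards must be positive, one per subtype")
  stopifnot_cfg(all(c(cfg$noise_sd, cfg$subtype_effect_sd,
                      cfg$plex_offset_sd, cfg$loading_mass_slope_sd) >= 0),
                "sds must be >= 0")
  for (d in cfg$drug_specs) {
    stopifnot_cfg(!is.null(d$name) && is.numeric(d$baseline),
                  "each drug spec needs a name and numeric baseline")
    stopifnot_cfg(d$fraction > 0 && d$fraction <= 1,
                  "drug fraction assayed must be in (0,1]")
  }
  invisible(cfg)
}

#' Generate a synthetic multiomic cohort
#'
#' Draws a cohort with planted subtype structure shared across mRNA, global
#' proteome and phosphoproteome, plus the technical artifacts the
#' preprocessing stage must remove: per-plex batch offsets and a continuous
#' loading-mass effect. Each modality is
#' `subtype mean + plex offset + slope x (mass - mean mass) + noise`,
#' then thinned by missing-completely-at-random deletion at `missing_rate`
#' and an intensity-dependent (logistic in the value's z-score) component
#' scaled by `mnar_strength`. Mutations, drug AUCs and survival are drawn
#' conditional on the planted subtype.
#'
#' @param config a [synthetic_config()].
#' @return `synthetic_cohort` list with elements `omics` (named list of
#'   feature x sample matrices, NA = missing), `annotation` (data.frame with
#'   sample, plex, loading_mass, mutation flags, survival_time,
#'   survival_event), `drugs` (samples x drugs AUC matrix, NA = not assayed),
#'   `truth_labels` (planted subtype per sample) and `truth_effects` (per
#'   modality, the features x subtypes planted mean matrix).
#' @export
#' @examples
#' cohort <- generate_cohort(synthetic_config(n_samples = 24, seed = 7,
#'   n_features = c(mrna = 30, protein = 30, phospho = 20)))
#' sapply(cohort$omics, dim)
generate_cohort <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  set.seed(config$seed)
  n <- config$n_samples
  k <- config$k_true
  samples <- sprintf("S%03d", seq_len(n))

  truth <- sample(rep_len(seq_len(k), n))
  plex <- factor(rep_len(seq_len(config$n_plexes), n),
                 levels = seq_len(config$n_plexes))
  mass <- stats::runif(n, 30, 70)
  mass_c <- mass - mean(mass)

  omics <- list()
  truth_effects <- list()
  for (mod in c("mrna", "protein", "phospho")) {
    p <- config$n_features[[mod]]
    feats <- sprintf("%s_f%04d", mod, seq_len(p))
    mu <- matrix(stats::rnorm(p * k, 0, config$subtype_effect_sd), p, k,
                 dimnames = list(feats, paste0("subtype", seq_len(k))))
    x <- mu[, truth, drop = FALSE]
    plex_off <- matrix(stats::rnorm(p * config$n_plexes, 0,
                                    config$plex_offset_sd),
                       p, config$n_plexes)
    x <- x + plex_off[, as.integer(plex), drop = FALSE]
    slope <- stats::rnorm(p, config$loading_mass_slope_mean,
                          config$loading_mass_slope_sd)
    x <- x + outer(slope, mass_c)
    x <- x + matrix(stats::rnorm(p * n, 0, config$noise_sd), p, n)
    dimnames(x) <- list(feats, samples)

    p_miss <- matrix(config$missing_rate, p, n)
    if (config$mnar_strength > 0) {
      z <- (x - mean(x)) / stats::sd(x)
      p_miss <- p_miss + (1 - config$missing_rate) *
        config$mnar_strength * stats::plogis(-2 * z)
    }
    p_miss <- pmin(p_miss, 0.95)
    x[matrix(stats::runif(p * n), p, n) < p_miss] <- NA
    omics[[mod]] <- x
    truth_effects[[mod]] <- mu
  }

  genes <- rownames(config$mutation_rates)
  mutations <- sapply(genes, function(g)
    as.integer(stats::runif(n) < config$mutation_rates[g, truth]))
  rownames(mutations) <- samples

  base_rate <- 1 / 500  # per day; median OS ~ 1 year at hazard 1
  time <- stats::rexp(n, base_rate * config$survival_hazards[truth])
  cens <- stats::runif(n, 0, 1500)
  annotation <- data.frame(
    sample = samples, plex = plex, loading_mass = mass,
    as.data.frame(mutations),
    survival_time = pmin(time, cens),
    survival_event = as.integer(time <= cens),
    row.names = samples, check.names = FALSE)

  drugs <- generate_drug_response(truth, mutations, config$drug_specs,
                                  seed = config$seed + 1L)

  structure(list(omics = omics, annotation = annotation, drugs = drugs,
                 truth_labels = stats::setNames(truth, samples),
                 truth_effects = truth_effects, config = config),
            class = "synthetic_cohort")
}

#' Generate a sparse sample x drug AUC table
#'
#' AUC = clamp(baseline + subtype shift + mutation shift(s) + optional
#' subtype-restricted interaction shift + Gaussian noise, 1, 300); each drug
#' is assayed only on its stated fraction of samples, emulating the sparsity
#' of ex vivo screening panels.
#'
#' @param truth_labels planted subtype per sample (integer vector, named).
#' @param mutations samples x genes 0/1 matrix (may be NULL when no spec uses
#'   mutation shifts).
#' @param drug_specs list of drug specifications ([default_drug_specs()]).
#' @param seed integer seed.
#' @return samples x drugs numeric matrix in [1, 300], NA = not assayed.
#' @export
generate_drug_response <- function(truth_labels, mutations, drug_specs,
                                   seed = 1) {
  if (!length(drug_specs)) stop("drug_specs must be nonempty", call. = FALSE)
  set.seed(as.integer(seed))
  n <- length(truth_labels)
  samples <- names(truth_labels) %||% sprintf("S%03d", seq_len(n))
  out <- matrix(NA_real_, n, length(drug_specs),
                dimnames = list(samples,
                                vapply(drug_specs, `[[`, "", "name")))
  for (j in seq_along(drug_specs)) {
    d <- drug_specs[[j]]
    auc <- rep(d$baseline, n)
    if (!is.null(d$subtype_shift) && any(d$subtype_shift != 0))
      auc <- auc + d$subtype_shift[truth_labels]
    for (g in names(d$mutation_shift))
      auc <- auc + d$mutation_shift[[g]] * mutations[, g]
    if (!is.null(d$interaction)) {
      ix <- d$interaction
      hit <- truth_labels == ix$subtype & mutations[, ix$gene] == 1
      auc <- auc + ifelse(hit, ix$shift, 0)
    }
    if (d$noise_sd > 0) auc <- auc + stats::rnorm(n, 0, d$noise_sd)
    auc <- pmin(pmax(auc, 1), 300)
    assayed <- sample.int(n, round(d$fraction * n))
    out[assayed, j] <- auc[assayed]
  }
  out
}

#' Generate synthetic gene sets and a kinase-substrate map
#'
#' Random gene sets drawn from the supplied feature universe (overlap
#' allowed) and a kinase-substrate map assigning each kinase a random set of
#' phosphosite substrates; fixtures for the enrichment stage.
#'
#' @param feature_ids universe of feature ids for gene sets.
#' @param n_sets number of gene sets.
#' @param n_kinases number of kinases.
#' @param seed integer seed.
#' @param set_size inclusive size range for gene sets.
#' @param substrates_per_kinase inclusive size range for substrate sets.
#' @param phospho_ids universe for substrates (defaults to `feature_ids`).
#' @return list with `gene_sets` (named list of id vectors) and
#'   `kinase_substrate` (data.frame with columns kinase, substrate).
#' @export
generate_pathway_resources <- function(feature_ids, n_sets = 20,
                                       n_kinases = 10, seed = 1,
                                       set_size = c(5, 30),
                                       substrates_per_kinase = c(5, 20),
                                       phospho_ids = feature_ids) {
  if (max(set_size) > length(feature_ids))
    stop("requested set size exceeds feature count", call. = FALSE)
  if (max(substrates_per_kinase) > length(phospho_ids))
    stop("requested substrate count exceeds phosphosite count", call. = FALSE)
  set.seed(as.integer(seed))
  sizes <- if (set_size[1] == set_size[2]) rep(set_size[1], n_sets)
           else sample(set_size[1]:set_size[2], n_sets, replace = TRUE)
  gene_sets <- lapply(sizes, function(sz) sample(feature_ids, sz))
  names(gene_sets) <- sprintf("set%02d", seq_len(n_sets))
  ks <- do.call(rbind, lapply(seq_len(n_kinases), function(i) {
    sz <- if (substrates_per_kinase[1] == substrates_per_kinase[2])
      substrates_per_kinase[1]
    else sample(substrates_per_kinase[1]:substrates_per_kinase[2], 1)
    data.frame(kinase = sprintf("kin%02d", i),
               substrate = sample(phospho_ids, sz))
  }))
  list(gene_sets = gene_sets, kinase_substrate = ks)
}

#' Generate a drug-resistance trajectory between two subtypes
#'
#' Emulates a cell-line series drifting from one subtype's expression program
#' to another's (naive through late resistance): stage s of `n_stages`
#' interpolates linearly between the two planted subtype mean profiles, with
#' low within-stage noise reflecting cell-line homogeneity.
#'
#' @param cohort a `synthetic_cohort` supplying the planted subtype means.
#' @param from_subtype,to_subtype subtype indices (<= k_true).
#' @param n_stages number of stages (>= 2); stage 1 sits at `from_subtype`,
#'   the final stage at `to_subtype`.
#' @param n_reps replicate samples per stage.
#' @param seed integer seed.
#' @param modality which modality's mean profiles to interpolate.
#' @param noise_sd within-stage replicate noise sd.
#' @return list with `matrix` (features x (n_stages * n_reps)) and `stage`
#'   (integer stage per column, 1-based).
#' @export
generate_resistance_trajectory <- function(cohort, from_subtype, to_subtype,
                                           n_stages = 3, n_reps = 4, seed = 1,
                                           modality = "protein",
                                           noise_sd = 0.1) {
  k <- cohort$config$k_true
  if (from_subtype > k || to_subtype > k)
    stop("subtype indices must be <= k_true", call. = FALSE)
  if (n_stages < 2) stop("n_stages must be >= 2", call. = FALSE)
  set.seed(as.integer(seed))
  mu <- cohort$truth_effects[[modality]]
  frac <- seq(0, 1, length.out = n_stages)
  cols <- lapply(seq_len(n_stages), function(s) {
    center <- (1 - frac[s]) * mu[, from_subtype] + frac[s] * mu[, to_subtype]
    center + matrix(stats::rnorm(nrow(mu) * n_reps, 0, noise_sd),
                    nrow(mu), n_reps)
  })
  x <- do.call(cbind, cols)
  dimnames(x) <- list(rownames(mu),
                      sprintf("stage%d_rep%d", rep(seq_len(n_stages),
                                                   each = n_reps),
                              rep(seq_len(n_reps), n_stages)))
  list(matrix = x, stage = rep(seq_len(n_stages), each = n_reps))
}
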