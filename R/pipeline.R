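default_pipeline_config <- function() {
  list(
    seed = 1,
    stages = list(simulate = TRUE, preprocess = TRUE, subtype = TRUE,
                  classify = TRUE, enrich = TRUE, stratify = TRUE,
                  model_drugs = TRUE),
    simulate = list(),                      # synthetic_config() overrides
    preprocess = list(max_missing_frac = 0.5, knn_k = 10,
                      covariates = c("loading_mass", "plex")),
    subtype = list(k = NULL, k_range = 2:8, n_runs = 30,
                   max_iter = 200, tol = 1e-4),
    classify = list(alpha = 0.9),
    enrich = list(n_sets = 15, n_kinases = 8, n_perm = 500),
    stratify = list(min_tested = 50, min_sensitive = 5,
                    sens_threshold = 100),
    model_drugs = list(model = "en", repeats = 2, folds = 5)
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  utils::modifyList(default_pipeline_config(), config)
}

#' Run the full subtype discovery and drug-response pipeline
#'
#' Executes the stages in dependency order — simulate (or load), preprocess
#' (missingness filter, KNN imputation, empirical-Bayes covariate
#' correction), subtype (signed-split NMF consensus clustering with
#' cophenetic k selection), classify (multinomial elastic net on the
#' proteome), enrich (GSEA/KSEA per subtype on synthetic resources),
#' stratify (drug filter, Welch associations, Fisher enrichment, survival)
#' and model_drugs (per-drug repeated-CV regression + signature) — writing
#' each stage's outputs as TSV under `out_dir` plus a JSON run manifest with
#' seeds, parameters and file checksums. Rerunning the same configuration
#' reproduces identical outputs.
#'
#' @param config configuration list or YAML path; unset fields take the
#'   built-in defaults. Set `config$stages$<stage>` to FALSE to skip a
#'   stage; input paths (`global`, `phospho`, `mrna`, `annotation`,
#'   `drugs`) may replace the simulate stage.
#' @param out_dir output directory (created if needed).
#' @return the manifest (invisibly), also written to `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- read_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("proteosubtype")),
    seed = cfg$seed, parameters = cfg[setdiff(names(cfg), "stages")],
    stages_run = character(0), files = list())
  out <- function(name) file.path(out_dir, name)
  note <- function(stage) {
    manifest$stages_run <<- c(manifest$stages_run, stage)
    message("[", stage, "] done")
  }

  if (isTRUE(cfg$stages$simulate)) {
    sim_cfg <- do.call(synthetic_config,
                       utils::modifyList(list(seed = cfg$seed),
                                         cfg$simulate))
    cohort <- generate_cohort(sim_cfg)
    for (mod in names(cohort$omics))
      write_omics_matrix(cohort$omics[[mod]], out(paste0(mod, ".tsv")))
    utils::write.table(cohort$annotation, out("annotation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_drug_table(cohort$drugs, out("drugs.tsv"))
    utils::write.table(
      data.frame(sample = names(cohort$truth_labels),
                 subtype = cohort$truth_labels),
      out("truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    omics <- cohort$omics
    annotation <- cohort$annotation
    drugs <- cohort$drugs
    note("simulate")
  } else {
    omics <- list()
    for (mod in c("mrna", "global", "phospho"))
      if (!is.null(cfg[[mod]])) {
        key <- if (mod == "global") "protein" else mod
        omics[[key]] <- read_omics_matrix(cfg[[mod]])
      }
    annotation <- if (!is.null(cfg$annotation)) read_annotation(cfg$annotation)
    drugs <- if (!is.null(cfg$drugs)) read_drug_table(cfg$drugs)
  }

  if (isTRUE(cfg$stages$preprocess)) {
    pp <- cfg$preprocess
    omics <- lapply(omics, function(m) {
      m <- filter_missingness(m, pp$max_missing_frac)
      m <- knn_impute(m, k = pp$knn_k)
      eb_covariate_correction(m, annotation, covariates = pp$covariates)
    })
    for (mod in names(omics))
      write_omics_matrix(omics[[mod]], out(paste0(mod, "_corrected.tsv")))
    note("preprocess")
  }

  labels <- NULL
  if (isTRUE(cfg$stages$subtype)) {
    st <- cfg$subtype
    split <- standardize_and_split(omics)
    if (is.null(st$k)) {
      sel <- select_k(split, k_range = st$k_range, n_runs = st$n_runs,
                      seed = cfg$seed, max_iter = st$max_iter, tol = st$tol)
      utils::write.table(sel$curve, out("cophenetic_curve.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      cons <- sel$results[[as.character(sel$k_best)]]
    } else {
      cons <- consensus_cluster(split, st$k, n_runs = st$n_runs,
                                seed = cfg$seed, max_iter = st$max_iter,
                                tol = st$tol)
    }
    labels <- cons$labels
    write_omics_matrix(cons$A, out("consensus_matrix.tsv"))
    utils::write.table(data.frame(sample = names(labels), subtype = labels),
                       out("subtypes.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("subtype")
  }

  if (isTRUE(cfg$stages$classify)) {
    model <- fit_multinomial_elasticnet(omics$protein, labels,
                                        alpha = cfg$classify$alpha,
                                        seed = cfg$seed)
    pred <- predict_proba(model, omics$protein)
    utils::write.table(
      data.frame(sample = rownames(pred$prob), pred$prob,
                 predicted = as.character(pred$labels)),
      out("classifier_predictions.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    sig <- extract_signature(model)
    utils::write.table(sig, out("classifier_signature.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("classify")
  }

  if (isTRUE(cfg$stages$enrich)) {
    en <- cfg$enrich
    res <- generate_pathway_resources(
      rownames(omics$protein), n_sets = en$n_sets,
      n_kinases = en$n_kinases, seed = cfg$seed,
      phospho_ids = rownames(omics$phospho))
    enr <- do.call(rbind, lapply(sort(unique(labels)), function(st) {
      rv <- subtype_rank_vector(omics$protein, labels, st)
      g <- gsea_preranked(rv, res$gene_sets, n_perm = en$n_perm,
                          seed = cfg$seed)
      if (nrow(g)) cbind(subtype = st, g)
    }))
    utils::write.table(enr, out("gsea.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ks <- do.call(rbind, lapply(sort(unique(labels)), function(st) {
      rv <- subtype_rank_vector(omics$phospho, labels, st)
      cbind(subtype = st, ksea(rv, res$kinase_substrate))
    }))
    utils::write.table(ks, out("ksea.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    note("enrich")
  }

  if (isTRUE(cfg$stages$stratify)) {
    stf <- cfg$stratify
    kept <- filter_drugs(drugs, stf$min_tested, stf$min_sensitive,
                         stf$sens_threshold)
    kept <- kept[names(labels), , drop = FALSE]
    assoc <- welch_association(kept, factor(labels))
    utils::write.table(assoc, out("drug_subtype_association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    mut_cols <- intersect(c("FLT3", "NPM1", "TP53"), colnames(annotation))
    if (length(mut_cols)) {
      fish <- fisher_enrichment(labels,
                                annotation[names(labels), mut_cols,
                                           drop = FALSE])
      utils::write.table(fish, out("mutation_enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    surv <- km_logrank(annotation[names(labels), , drop = FALSE], labels)
    utils::write.table(
      data.frame(chisq = surv$chisq, df = surv$df, p = surv$p),
      out("survival_logrank.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    note("stratify")
  }

  if (isTRUE(cfg$stages$model_drugs)) {
    md <- cfg$model_drugs
    kept <- filter_drugs(drugs, cfg$stratify$min_tested,
                         cfg$stratify$min_sensitive,
                         cfg$stratify$sens_threshold)
    evals <- do.call(rbind, lapply(colnames(kept), function(d) {
      ev <- repeated_cv_evaluate(omics$protein, kept[, d], model = md$model,
                                 repeats = md$repeats, folds = md$folds,
                                 seed = cfg$seed)
      cbind(drug = d, ev)
    }))
    utils::write.table(evals, out("drug_model_cv.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    sigs <- do.call(rbind, lapply(colnames(kept), function(d) {
      s <- final_signature(omics$protein, kept[, d], model = md$model,
                           seed = cfg$seed)
      if (nrow(s)) cbind(drug = d, s)
    }))
    utils::write.table(sigs, out("drug_signatures.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("model_drugs")
  }

  files <- list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE)
  manifest$files <- as.list(tools::md5sum(files))
  names(manifest$files) <- basename(files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
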