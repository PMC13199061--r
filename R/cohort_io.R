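#' Write a cohort to plain-text files
#'
#' Writes `clinical.csv`, `mutations.csv` (binary), `outcomes.csv`
#' (`patient_id`, `time`, `event`), `tile_embeddings.csv` (long-format
#' store) and, for synthetic cohorts, `ground_truth.json` (generating
#' coefficients and seed).
#'
#' @param cohort a `cms_cohort`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- cohort$patient_ids
  write.csv(data.frame(patient_id = ids, cohort$clinical_table,
                       check.names = FALSE),
            file.path(dir, "clinical.csv"), row.names = FALSE)
  write.csv(data.frame(patient_id = ids, cohort$mutation_matrix,
                       check.names = FALSE),
            file.path(dir, "mutations.csv"), row.names = FALSE)
  write.csv(data.frame(patient_id = ids, time = cohort$outcomes$time,
                       event = cohort$outcomes$event),
            file.path(dir, "outcomes.csv"), row.names = FALSE)
  write_tile_embeddings(cohort$tile_embeddings,
                        file.path(dir, "tile_embeddings.csv"))
  if (!is.null(cohort$true_coefficients)) {
    jsonlite::write_json(
      list(true_coefficients = cohort$true_coefficients,
           risk_class = cohort$risk_class,
           true_linear_predictor = cohort$true_linear_predictor,
           seed = cohort$config$seed),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Assemble a cohort from standard files
#'
#' Inner-joins the clinical, mutation, outcome and tile-embedding sources
#' on patient id; patients missing from any source are excluded and
#' reported. Outcomes are validated (`time > 0`, `event` binary).
#' Positional alignment is never used — the id is the sole join key and
#' the result is ordered by id.
#'
#' @param clinical_csv,mutations_csv,outcomes_csv,embeddings_csv file
#'   paths; `mutations_csv` may instead be a MAF file (`maf = TRUE`).
#' @param id_column name of the patient-id column in the CSV sources.
#' @param maf treat `mutations_csv` as MAF format?
#' @return list of class `cms_cohort` with an `exclusions` element
#'   (data frame: `patient_id`, `missing_from`).
#' @export
load_cohort <- function(clinical_csv, mutations_csv, outcomes_csv,
                        embeddings_csv, id_column = "patient_id",
                        maf = FALSE) {
  read_tab <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!id_column %in% names(df))
      stop_cms(path, " lacks id column '", id_column, "'")
    if (anyDuplicated(df[[id_column]]))
      stop_cms("duplicate patient ids in ", path)
    df
  }
  clin <- read_tab(clinical_csv)
  out <- read_tab(outcomes_csv)
  if (maf) {
    mut_m <- read_maf_binary(mutations_csv)
    mut_ids <- rownames(mut_m)
  } else {
    mut <- read_tab(mutations_csv)
    mut_m <- as.matrix(mut[, setdiff(names(mut), id_column), drop = FALSE])
    rownames(mut_m) <- mut[[id_column]]
    mut_ids <- mut[[id_column]]
  }
  emb <- load_tile_embeddings(embeddings_csv)
  sources <- list(clinical = clin[[id_column]], mutations = mut_ids,
                  outcomes = out[[id_column]], embeddings = names(emb))
  ids <- sort(Reduce(intersect, sources))
  if (!length(ids)) stop_cms("no patients present in all sources")
  all_ids <- sort(unique(unlist(sources)))
  excl <- do.call(rbind, lapply(all_ids[!all_ids %in% ids], function(id) {
    data.frame(patient_id = id,
               missing_from = paste(names(sources)[
                 !vapply(sources, function(s) id %in% s, logical(1))],
                 collapse = ";"))
  })) %||% data.frame(patient_id = character(), missing_from = character())

  oc <- out[match(ids, out[[id_column]]), ]
  bad <- which(!is.finite(oc$time) | oc$time <= 0)
  if (length(bad))
    stop_cms("invalid survival time for patient(s): ",
             paste(ids[bad], collapse = ", "))
  if (!all(oc$event %in% c(0, 1)))
    stop_cms("event indicator must be 0/1")
  if (!all(mut_m %in% c(0, 1)))
    stop_cms("mutation matrix must be binary 0/1")

  clin_rows <- clin[match(ids, clin[[id_column]]),
                    setdiff(names(clin), id_column), drop = FALSE]
  rownames(clin_rows) <- ids
  structure(list(
    patient_ids = ids,
    mutation_matrix = mut_m[match(ids, rownames(mut_m)), , drop = FALSE],
    clinical_table = clin_rows,
    tile_embeddings = emb[ids],
    outcomes = data.frame(time = oc$time, event = oc$event, row.names = ids),
    exclusions = excl), class = "cms_cohort")
}

#' Run a full experiment: simulate, cross-validate, evaluate, interpret
#'
#' Executes the package's end-to-end protocol on a synthetic cohort:
#' generation, event-stratified 5-fold cross-validation of the three-stage
#' pipeline, fold-model ensembling, median-split risk stratification with
#' log-rank, silhouette comparison before/after contrastive alignment with
#' a paired fold t-test, and the LASSO-then-OLS importance analysis of the
#' non-image features against the ensemble risk. All results and the
#' resolved configuration are written as JSON under `out_dir`.
#'
#' @param sim_config a [simulation_config()] (or `NULL` for defaults).
#' @param train_config a [training_config()].
#' @param out_dir output directory; created. `NULL` skips writing.
#' @param k folds.
#' @param n_boot bootstrap replicates for confidence intervals.
#' @return list with `cohort`, `cv`, `ensemble`, `report` (named list of
#'   scalar statistics).
#' @export
run_experiment <- function(sim_config = NULL, train_config = NULL,
                           out_dir = NULL, k = 5, n_boot = 200) {
  sim_config <- sim_config %||% simulation_config()
  train_config <- train_config %||% training_config(seed = sim_config$seed)
  cohort <- generate_cohort(sim_config)
  folds <- make_folds(cohort$outcomes, k, seed = train_config$seed)
  cv <- cross_validate(cohort, train_config, folds)
  ens <- ensemble_risk(cv, cohort)
  strat <- median_split_logrank(ens, cohort$outcomes)
  boot <- bootstrap_ci(cv$val_risk, cohort$outcomes, n_boot = max(n_boot, 100),
                       seed = train_config$seed)
  sil_t <- paired_fold_ttest(cv$silhouette$pre, cv$silhouette$post)

  # interpret the model: non-image features against the ensemble risk
  prep0 <- fit_fold_features(cohort, seq_along(cohort$patient_ids))
  feats <- cbind(
    align_mutation_features(cohort$mutation_matrix, prep0$selected),
    build_feature_matrix(cohort$clinical_table,
                         state = prep0$clin_state)$features)
  imp <- tryCatch(
    lasso_ols_importance(feats, ens, seed = train_config$seed),
    error = function(e) NULL)

  report <- list(
    n_patients = length(cohort$patient_ids),
    event_rate = mean(cohort$outcomes$event),
    cv_c_index_fused = mean(cv$c_index$fused, na.rm = TRUE),
    cv_c_index_image = mean(cv$c_index$image, na.rm = TRUE),
    cv_c_index_nonimage = mean(cv$c_index$nonimage, na.rm = TRUE),
    pooled_c_index = boot$point,
    pooled_c_index_low = boot$low, pooled_c_index_high = boot$high,
    ensemble_c_index = concordance_index(ens, cohort$outcomes),
    logrank_statistic = strat$statistic,
    logrank_p = strat$p_value,
    silhouette_pre = mean(cv$silhouette$pre, na.rm = TRUE),
    silhouette_post = mean(cv$silhouette$post, na.rm = TRUE),
    silhouette_ttest_p = sil_t$p_value,
    cosine_pre = mean(cv$cosine$pre), cosine_post = mean(cv$cosine$post),
    seed = train_config$seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(simulation = unclass(sim_config)[
        setdiff(names(sim_config), "clinical_schema")],
        epochs = as.list(train_config$epochs),
        batch_size = train_config$batch_size,
        learning_rate = train_config$learning_rate,
        temperature = train_config$contrastive$temperature,
        lambda_weight = train_config$contrastive$lambda_weight,
        seed = train_config$seed),
      file.path(out_dir, "resolved_config.json"), auto_unbox = TRUE,
      digits = NA)
    write.csv(data.frame(patient_id = cohort$patient_ids,
                         fold = folds$assignments,
                         ensemble_risk = unname(ens),
                         cv_risk = unname(cv$val_risk)),
              file.path(out_dir, "risks.csv"), row.names = FALSE)
    if (!is.null(imp))
      write.csv(imp, file.path(out_dir, "importance.csv"), row.names = FALSE)
  }
  list(cohort = cohort, cv = cv, ensemble = ens, importance = imp,
       report = report)
}
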