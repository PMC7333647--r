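# Configuration and end-to-end orchestration: simulate -> genomics ->
# associations/survival -> extract -> select -> evaluate -> exemplars,
# with a hashed artifact manifest for reproducibility checks.

#' Pipeline configuration
#'
#' Gathers every tunable constant of the analysis in one place (the "paper
#' profile" defaults): the simulation config, the transform bank, gray-level
#' discretization, selection (5-fold CV, 100 repetitions), evaluation (1000
#' stratified 80/20 splits, alpha 0.05), and the calling thresholds (segment
#' mean -0.2; gene-frequency screens 5% for the genomic cohort and 10% for
#' the smaller imaging cohort; survival-screen p cutoff 0.1).
#'
#' @param sim a [sim_config()].
#' @param transforms transform labels for feature extraction.
#' @param n_bins gray-level bins.
#' @param selection list: `folds`, `repetitions`.
#' @param evaluation list: `repetitions`, `test_fraction`, `alpha`.
#' @param thresholds list: `seg_mean`, `gene_freq`, `gene_freq_imaging`,
#'   `p_cutoff`, `p_survival`.
#' @param seed master seed (also overrides `sim$seed`).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            transforms = default_transform_labels(),
                            n_bins = 16L,
                            selection = list(folds = 5L, repetitions = 100L),
                            evaluation = list(repetitions = 1000L,
                                              test_fraction = 0.2,
                                              alpha = 0.05),
                            thresholds = list(seg_mean = -0.2,
                                              gene_freq = 0.05,
                                              gene_freq_imaging = 0.10,
                                              p_cutoff = 0.05,
                                              p_survival = 0.1),
                            seed = 1L) {
  stopifnot(inherits(sim, "sim_config"))
  if (evaluation$test_fraction <= 0 || evaluation$test_fraction >= 1) {
    stop_cfg("test_fraction must be in (0, 1)")
  }
  check_fraction(evaluation$alpha, "alpha")
  check_fraction(thresholds$gene_freq, "gene_freq")
  if (thresholds$seg_mean > 0) stop_cfg("seg_mean threshold must be <= 0")
  sim$seed <- as.integer(seed)
  structure(list(sim = sim, transforms = transforms,
                 n_bins = as.integer(n_bins),
                 selection = selection, evaluation = evaluation,
                 thresholds = thresholds, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' JSON round-trip is lossless for every field.
#'
#' @param config a `pipeline_config`.
#' @param path JSON path.
#' @return `read_pipeline_config`: the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass_config(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

unclass_config <- function(config) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  out
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- do.call(sim_config, raw$sim)
  pipeline_config(sim = sim, transforms = raw$transforms,
                  n_bins = raw$n_bins, selection = raw$selection,
                  evaluation = raw$evaluation, thresholds = raw$thresholds,
                  seed = raw$seed)
}

#' Screen a cohort for complete image and genomic data
#'
#' A patient is included iff all four MR sequences are present in the image
#' inventory and a genomic record exists; every exclusion is logged with one
#' reason.
#'
#' @param image_inventory data.frame with columns `patient_id`, `sequence`.
#' @param genomic_ids character vector of patients with genomic data.
#' @return list with `included` (character) and `exclusions`
#'   (data.frame patient/reason).
#' @export
screen_cohort <- function(image_inventory, genomic_ids) {
  seqs <- c("T1pre", "T1post", "T2", "FLAIR")
  pats <- unique(image_inventory$patient_id)
  included <- character(0)
  excl <- list()
  for (p in pats) {
    have <- image_inventory$sequence[image_inventory$patient_id == p]
    missing <- setdiff(seqs, have)
    if (length(missing)) {
      excl[[p]] <- paste("missing sequence:", paste(missing, collapse = "+"))
    } else if (!p %in% genomic_ids) {
      excl[[p]] <- "missing genomic data"
    } else {
      included <- c(included, p)
    }
  }
  list(included = included,
       exclusions = data.frame(patient = names(excl),
                               reason = unlist(excl, use.names = FALSE),
                               stringsAsFactors = FALSE))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes simulate -> genomic recovery -> association/survival statistics
#' -> image synthesis -> feature extraction -> stability selection ->
#' repeated-split evaluation -> U-test screening and exemplar selection,
#' writing all declared artifacts plus `manifest.json` with the config, the
#' seed and an MD5 per artifact. Re-running with the same config and seed
#' reproduces every hash.
#'
#' @param config a [pipeline_config()].
#' @param out_dir artifact directory (created if needed).
#' @param write_images also write per-patient NIfTI volumes.
#' @param verbose log stage progress.
#' @return path to `manifest.json`, invisibly; the manifest list as the
#'   `manifest` attribute.
#' @export
run_pipeline <- function(config, out_dir, write_images = TRUE,
                         verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[pipeline] ", ...)
  artifacts <- character(0)

  say("simulate genomic cohort")
  gen <- generate_genomic_cohort(config$sim)
  say("simulate image cohort")
  imgs <- generate_image_cohort(config$sim, gen$truth$cic)
  masks <- lapply(imgs, `[[`, "mask")
  paths <- write_cohort(gen, if (write_images) imgs else NULL, out_dir)
  artifacts <- c(artifacts, unname(paths))

  say("genomic status recovery")
  status <- genomic_status_table(gen$variants, gen$segments,
                                 gen$cohort$patient_id)
  artifacts <- c(artifacts, write_tsv(status, file.path(out_dir, "status.tsv")))
  screen <- mutation_frequency_screen(gen$variants, gen$cohort$patient_id,
                                      config$thresholds$gene_freq)
  artifacts <- c(artifacts, write_tsv(screen, file.path(out_dir,
                                                        "gene_screen.tsv")))

  say("association and survival statistics")
  ct <- table(factor(gen$cohort$grade, levels = c("G2", "G3")),
              factor(gen$cohort$cic, levels = c(1, 0)))
  chi <- tryCatch(pearson_chi2(unclass(ct)), error = function(e) NULL)
  surv_df <- data.frame(time = gen$cohort$os_days,
                        event = gen$cohort$os_event,
                        cic = gen$cohort$cic, age = gen$cohort$age,
                        grade = as.integer(gen$cohort$grade == "G3"),
                        idh = gen$cohort$idh, codel = gen$cohort$codel,
                        fubp1 = gen$cohort$fubp1)
  km_mut <- km_estimate(surv_df$time[surv_df$cic == 1],
                        surv_df$event[surv_df$cic == 1])
  km_wt <- km_estimate(surv_df$time[surv_df$cic == 0],
                       surv_df$event[surv_df$cic == 0])
  lr <- logrank_test(surv_df$time, surv_df$event, surv_df$cic)
  cox <- tryCatch(
    cox_fit(surv_df, c("cic", "age", "grade", "idh", "codel", "fubp1")),
    error = function(e) NULL)
  assoc <- list(
    chi2_grade = if (is.null(chi)) NULL else chi[c("statistic", "df", "p")],
    km_median_cic_mut = km_mut$median,
    km_median_cic_wt = km_wt$median,
    logrank = lr,
    cox = if (is.null(cox)) NULL else cox$table)
  assoc_path <- file.path(out_dir, "assoc.json")
  jsonlite::write_json(assoc, assoc_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", force = TRUE)
  artifacts <- c(artifacts, assoc_path)

  say("feature extraction (", length(config$transforms), " transforms)")
  X <- extract_feature_table(imgs, transforms = config$transforms,
                             n_bins = config$n_bins)
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  X_use <- X[, keep, drop = FALSE]
  feat_path <- file.path(out_dir, "features.csv")
  utils::write.csv(as.data.frame(X), feat_path, row.names = TRUE)
  artifacts <- c(artifacts, feat_path)

  say("stability selection")
  y <- gen$truth$cic
  sel <- repeat_selection(X_use, y,
                          repetitions = config$selection$repetitions,
                          master_seed = derive_seed(config$seed, "select", 0L),
                          folds = config$selection$folds)
  retained <- truncate_top_sqrt_n(sel, nrow(X_use))
  sel_out <- as.data.frame(sel)
  sel_out$retained <- sel_out$feature %in% retained
  artifacts <- c(artifacts, write_tsv(sel_out,
                                      file.path(out_dir, "selection.tsv")))

  say("repeated-split evaluation")
  ev <- repeated_split_evaluate(
    X_use[, retained, drop = FALSE], y,
    repetitions = config$evaluation$repetitions,
    test_fraction = config$evaluation$test_fraction,
    master_seed = derive_seed(config$seed, "evaluate", 0L))
  eval_path <- file.path(out_dir, "evaluation.json")
  jsonlite::write_json(list(
    summary = as.data.frame(ev$summary),
    importance = as.list(ev$importance),
    roc = ev$roc[c("x", "y", "threshold", "auc")],
    pr = ev$pr[c("x", "y", "threshold", "auc")],
    roc_cutoff = ev$roc_cutoff, pr_cutoff = ev$pr_cutoff,
    mean_probability = stats::setNames(as.list(ev$mean_probability),
                                       rownames(X_use))),
    eval_path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  artifacts <- c(artifacts, eval_path)

  say("U-test screen and exemplars")
  ut <- u_test_and_top_third(X_use[, retained, drop = FALSE], y,
                             ev$importance, config$evaluation$alpha)
  artifacts <- c(artifacts, write_tsv(ut, file.path(out_dir, "u_test.tsv")))
  ex <- select_exemplars(X_use, ut$feature[ut$kept], ev$mean_probability,
                         masks)
  ex_path <- file.path(out_dir, "exemplars.json")
  jsonlite::write_json(ex, ex_path, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, ex_path)

  say("manifest")
  rel <- sub(paste0("^", normalizePath(out_dir), "/?"), "",
             normalizePath(artifacts))
  hashes <- unname(tools::md5sum(artifacts))
  ord <- order(rel)
  manifest <- list(
    package_version = as.character(utils::packageVersion("cicradiomics")),
    seed = config$seed,
    config = unclass_config(config),
    n_features_extracted = ncol(X),
    n_features_used = ncol(X_use),
    retained_features = retained,
    artifacts = data.frame(file = rel[ord], md5 = hashes[ord],
                           stringsAsFactors = FALSE))
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  out <- man_path
  attr(out, "manifest") <- manifest
  invisible(out)
}
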