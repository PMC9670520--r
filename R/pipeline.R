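# Stage orchestration. Each stage consumes only serialized artifacts of
# prior stages (files under the output directory), so stages can also be
# run individually from the analysis scripts.

# deterministic per-stage seed derived from the global seed and stage name;
# kept well below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 9973L
  (as.integer(seed) %% 200000L) * 10000L + h
}

#' Assemble a pipeline configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param vcf,sheet,gff Input paths; leave `NULL` with
#'   `simulate = TRUE` to generate them.
#' @param gmt Optional GMT path; enables the enrichment stage.
#' @param catalogue Optional somatic-catalogue path (VCF or TSV);
#'   enables the overlap stage.
#' @param sim A [sim_config()] used when `simulate = TRUE`.
#' @param simulate Generate synthetic discovery/validation inputs.
#' @param min_cases,require_unrelated Selection parameters.
#' @param pass_only Restrict to FILTER == PASS records.
#' @param importance_threshold,cv_folds,patience Feature-reduction
#'   parameters.
#' @param binarize,first_gene_only Feature-matrix toggles.
#' @param space A [tuning_space()] for classifier training.
#' @param seed Global seed, fanned out per stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, vcf = NULL, sheet = NULL, gff = NULL,
                            gmt = NULL, catalogue = NULL,
                            sim = sim_config(), simulate = is.null(vcf),
                            min_cases = 3L, require_unrelated = TRUE,
                            pass_only = FALSE,
                            importance_threshold = 1e-5, cv_folds = 5L,
                            patience = 1L, binarize = FALSE,
                            first_gene_only = FALSE,
                            space = tuning_space(), seed = 1L) {
  cfg <- as.list(environment())
  if (!simulate) {
    for (p in c("vcf", "sheet", "gff")) {
      if (is.null(cfg[[p]])) stop("configuration error: ", p,
                                  " path required unless simulate = TRUE")
    }
  }
  for (p in c("vcf", "sheet", "gff", "gmt", "catalogue")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("configuration error: ", p, " path does not exist: ", cfg[[p]])
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate (optional) -> annotate -> discover -> features ->
#' train -> predict -> compare-load -> enrich/overlap (optional),
#' writing each stage's artifacts plus a manifest JSON recording
#' inputs, effective parameter values, per-stage seeds and output
#' checksums. Any stage error aborts with the stage name; artifacts of
#' completed stages are retained.
#'
#' @param cfg A [pipeline_config()].
#' @return list with the main stage results and `manifest`, invisibly.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  outputs <- character(0)
  res <- list()
  run_stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    stages <<- c(stages, name)
    out
  }

  # -- simulate -------------------------------------------------------------
  if (cfg$simulate) {
    sim <- cfg$sim
    sim$seed <- stage_seed(cfg$seed, "simulate")
    gff <- file.path(cfg$out_dir, "genes.gff3")
    disc <- val <- NULL
    run_stage("simulate", function() {
      simulate_gene_model(sim, gff)
      model <- load_gene_model(gff)
      disc <<- simulate_cohort(sim, model, cfg$out_dir)
      val <<- simulate_validation(sim, disc$truth, cfg$out_dir)
      NULL
    })
    cfg$gff <- gff
    cfg$vcf <- disc$vcf
    cfg$sheet <- disc$sheet
    res$truth <- disc$truth
    res$validation_paths <- val
    outputs <- c(outputs, gff, disc$vcf, disc$sheet, val$vcf, val$sheet)
  }

  # -- annotate (gene model) ------------------------------------------------
  model <- run_stage("annotate", function() load_gene_model(cfg$gff))

  # -- discover -------------------------------------------------------------
  sel <- run_stage("discover", function() {
    cohort <- read_cohort(cfg$vcf, cfg$sheet, pass_only = cfg$pass_only)
    res$cohort <<- cohort
    s <- select_variants(cohort$matrix, cohort$sheet, min_cases = cfg$min_cases,
                         require_unrelated = cfg$require_unrelated)
    annotate_selection(s, model)
  })
  sel_path <- file.path(cfg$out_dir, "selection.tsv")
  write_selection(sel, sel_path)
  outputs <- c(outputs, sel_path)
  res$selection <- sel

  # -- features -------------------------------------------------------------
  strata <- c("coding", "noncoding", "intergenic")
  feats <- run_stage("features", function() {
    lapply(stats::setNames(strata, strata), function(st) {
      fm <- build_feature_matrix(sel, res$cohort$matrix, res$cohort$sheet, st,
                                 binarize = cfg$binarize,
                                 first_gene_only = cfg$first_gene_only)
      red <- if (length(fm$genes) >= 1L) {
        reduce_features(fm, importance_threshold = cfg$importance_threshold,
                        cv_folds = cfg$cv_folds, patience = cfg$patience,
                        seed = stage_seed(cfg$seed, paste0("features_", st)))
      } else NULL
      list(fm = fm, reduction = red)
    })
  })
  res$features <- feats
  for (st in strata) {
    fmp <- file.path(cfg$out_dir, paste0("features_", st, ".tsv"))
    utils::write.table(cbind(sample_id = feats[[st]]$fm$samples,
                             label = feats[[st]]$fm$labels,
                             as.data.frame(feats[[st]]$fm$load)),
                       fmp, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, fmp)
  }

  # -- train ----------------------------------------------------------------
  models <- run_stage("train", function() {
    lapply(stats::setNames(strata, strata), function(st) {
      red <- feats[[st]]$reduction
      genes <- if (is.null(red)) character(0) else red$kept_genes_final
      if (length(genes) < 1L) return(NULL)
      fm <- feats[[st]]$fm
      fm$load <- fm$load[, genes, drop = FALSE]
      fm$genes <- genes
      sp <- cfg$space
      sp$seed <- stage_seed(cfg$seed, paste0("train_", st))
      tune_and_train(fm, sp)
    })
  })
  res$models <- models

  # -- predict --------------------------------------------------------------
  if (!is.null(res$validation_paths)) {
    pred <- run_stage("predict", function() {
      vc <- read_cohort(res$validation_paths$vcf, res$validation_paths$sheet)
      res$val_cohort <<- vc
      fms <- lapply(stats::setNames(strata, strata), function(st) {
        genes <- if (is.null(models[[st]])) character(0) else models[[st]]$genes
        build_feature_matrix(sel, vc$matrix, vc$sheet, st, genes = genes,
                             binarize = cfg$binarize,
                             first_gene_only = cfg$first_gene_only)
      })
      predict_cohort(models, fms)
    })
    res$prediction <- pred
    pred_path <- file.path(cfg$out_dir, "predictions.tsv")
    utils::write.table(pred$per_sample, pred_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs <- c(outputs, pred_path)

    # -- compare-load -------------------------------------------------------
    res$load_comparison <- run_stage("compare_load", function() {
      mutation_load_compare(sel, res$val_cohort$matrix, res$val_cohort$sheet)
    })
  }

  # -- enrich ---------------------------------------------------------------
  if (!is.null(cfg$gmt)) {
    enr <- run_stage("enrich", function() {
      sets <- read_gmt(cfg$gmt)
      coll <- gene_set_collection(sets, universe = model$genes$gene_id)
      kept <- unique(unlist(lapply(strata, function(st) {
        r <- feats[[st]]$reduction
        if (is.null(r)) character(0) else r$kept_genes_final
      })))
      if (!length(kept)) return(NULL)
      hypergeom_enrich(kept, coll)
    })
    res$enrichment <- enr
    if (!is.null(enr)) {
      ep <- file.path(cfg$out_dir, "enrichment.tsv")
      utils::write.table(enr, ep, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, ep)
    }
  }

  # -- overlap --------------------------------------------------------------
  if (!is.null(cfg$catalogue)) {
    res$overlap <- run_stage("overlap", function() {
      catalogue_overlap(sel, read_catalogue(cfg$catalogue))
    })
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("bdvoi")),
    seed = cfg$seed,
    stage_seeds = stats::setNames(
      lapply(stages, function(s) stage_seed(cfg$seed, s)), stages),
    stages_complete = stages,
    parameters = list(min_cases = cfg$min_cases,
                      require_unrelated = cfg$require_unrelated,
                      pass_only = cfg$pass_only,
                      importance_threshold = cfg$importance_threshold,
                      cv_folds = cfg$cv_folds, patience = cfg$patience,
                      binarize = cfg$binarize,
                      first_gene_only = cfg$first_gene_only,
                      tuning_budget = cfg$space$budget),
    inputs = list(vcf = cfg$vcf, sheet = cfg$sheet, gff = cfg$gff,
                  gmt = cfg$gmt, catalogue = cfg$catalogue),
    output_checksums = as.list(tools::md5sum(outputs[file.exists(outputs)]))
  )
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  res$manifest <- manifest
  res$manifest_path <- manifest_path
  invisible(res)
}
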