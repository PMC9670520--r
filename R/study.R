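#' Run one simulated discovery + validation study end to end
#'
#' Generates a discovery cohort and an independent validation cohort,
#' applies the recurrence/exclusivity filter, builds and reduces
#' per-stratum gene-load features, trains the per-stratum MLP
#' classifiers, labels the validation cohort by majority vote, and
#' compares validation mutation loads between groups. Returns the
#' quantities the analysis reports: planted-signal recall, observed and
#' analytically expected spurious selections, per-stratum and combined
#' labeling accuracy, and the load comparison.
#'
#' @param seed Seed controlling every stochastic step of the run.
#' @param sim A [sim_config()]; its seed is overridden by `seed`.
#' @param tuning_budget Evaluations for each stratum's hyperparameter
#'   search.
#' @param permute_groups Permute the BD_CANCER / BD_ONLY group labels
#'   among discovery probands before variant selection (a null run: the
#'   whole pipeline, selection included, then operates on labels carrying
#'   no signal, and validation accuracy should be indistinguishable from
#'   chance). Permuting later — after the case-exclusive selection — is
#'   not a valid null: the selected features remain label-informative by
#'   construction.
#' @param keep_dir Optional directory to retain the simulated files in
#'   (a temporary directory is used and cleaned up otherwise).
#' @return list with `selection`, `recall`, `n_selected`, `n_spurious`,
#'   `expected_spurious`, `reduction` (per stratum), `prediction`,
#'   `load_comparison`, and `truth`.
#' @export
run_study <- function(seed, sim = sim_config(), tuning_budget = 6L,
                      permute_groups = FALSE, keep_dir = NULL) {
  dir <- if (is.null(keep_dir)) {
    d <- tempfile("bdvoi_study_")
    on.exit(unlink(d, recursive = TRUE), add = TRUE)
    d
  } else keep_dir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim$seed <- as.integer(seed)

  gff <- file.path(dir, "genes.gff3")
  simulate_gene_model(sim, gff)
  model <- load_gene_model(gff)
  disc <- simulate_cohort(sim, model, dir)
  val <- simulate_validation(sim, disc$truth, dir)

  co <- read_cohort(disc$vcf, disc$sheet)
  if (permute_groups) {
    set.seed(seed + 7777L)
    prob <- co$sheet$role == "proband" &
      co$sheet$group %in% c("BD_CANCER", "BD_ONLY")
    co$sheet$group[prob] <- sample(co$sheet$group[prob])
  }
  sel <- annotate_selection(select_variants(co$matrix, co$sheet), model)
  sig_ids <- if (is.null(disc$truth$signal)) character(0) else
    variant_key_id(disc$truth$signal)
  sel_ids <- variant_key_id(sel)
  recall <- if (length(sig_ids)) mean(sig_ids %in% sel_ids) else NA_real_
  n_spur <- sum(!sel_ids %in% sig_ids)
  exp_spur <- expected_spurious_selections(
    disc$truth$freqs, sim$n_case, sim$n_bd_only,
    disc$truth$n_case_with_control, disc$truth$n_bd_with_control)

  vc <- read_cohort(val$vcf, val$sheet)
  strata <- c("coding", "noncoding", "intergenic")
  models <- list()
  fms_val <- list()
  reductions <- list()
  for (st in strata) {
    fm <- build_feature_matrix(sel, co$matrix, co$sheet, st)
    if (length(fm$genes) < 1L || length(unique(fm$labels)) < 2L) next
    red <- reduce_features(fm, seed = stage_seed(seed, paste0("reduce_", st)))
    reductions[[st]] <- red
    genes <- red$kept_genes_final
    if (length(genes) < 1L) next
    fm$load <- fm$load[, genes, drop = FALSE]
    fm$genes <- genes
    sp <- tuning_space(budget = tuning_budget,
                       seed = stage_seed(seed, paste0("train_", st)))
    models[[st]] <- tune_and_train(fm, sp)
    fms_val[[st]] <- build_feature_matrix(sel, vc$matrix, vc$sheet, st,
                                          genes = genes)
  }
  pred <- if (length(models)) predict_cohort(models, fms_val) else NULL
  load_cmp <- mutation_load_compare(sel, vc$matrix, vc$sheet)

  list(selection = sel, recall = recall, n_selected = nrow(sel),
       n_spurious = n_spur, expected_spurious = exp_spur,
       reduction = reductions, prediction = pred,
       load_comparison = load_cmp, truth = disc$truth)
}
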