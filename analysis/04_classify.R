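#!/usr/bin/env Rscript

# Stage 4 — per-stratum MLP classifiers, majority-vote labeling of the
# validation cohort, and the mutation-load group comparison.
#
# Each stratum's classifier is tuned by sequential model-based
# optimization of cross-validated class-weighted log-loss, refit on the
# full discovery probands, and casts one vote per validation sample;
# the combined label is the majority of the three votes.

suppressMessages(library(bdvoi))

data_dir <- "results/data"
model <- load_gene_model(file.path(data_dir, "genes.gff3"))
co <- read_cohort(file.path(data_dir, "discovery.vcf"),
                  file.path(data_dir, "discovery_sheet.tsv"))
vc <- read_cohort(file.path(data_dir, "validation.vcf"),
                  file.path(data_dir, "validation_sheet.tsv"))
sel <- annotate_selection(select_variants(co$matrix, co$sheet), model)
red <- jsonlite::read_json("results/reduction.json", simplifyVector = TRUE)

strata <- c("coding", "noncoding", "intergenic")
models <- list()
fms_val <- list()
for (st in strata) {
  genes <- red[[st]]$kept
  if (length(genes) < 1L) next
  fm <- build_feature_matrix(sel, co$matrix, co$sheet, st, genes = genes)
  models[[st]] <- tune_and_train(
    fm, tuning_space(budget = 6L, seed = 100L + match(st, strata)))
  fms_val[[st]] <- build_feature_matrix(sel, vc$matrix, vc$sheet, st,
                                        genes = genes)
  message(st, ": trained on ", length(genes), " genes; best config: ",
          models[[st]]$best_params$hidden_layers, " hidden layer(s) x ",
          models[[st]]$best_params$neurons, " neurons, ",
          models[[st]]$best_params$activation, "/",
          models[[st]]$best_params$solver)
}

pred <- predict_cohort(models, fms_val)
print(pred)
write.table(pred$per_sample, "results/predictions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cmp <- mutation_load_compare(sel, vc$matrix, vc$sheet)
print(cmp)
jsonlite::write_json(list(summary = as.data.frame(cmp$summary),
                          medians = as.list(cmp$medians),
                          p_value = cmp$p_value),
                     "results/load_comparison.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("predictions and load comparison -> results/")
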