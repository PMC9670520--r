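#!/usr/bin/env Rscript

# Stage 1 — simulate the study inputs.
#
# Generates the default-scale study: a gene model on one contig, a
# discovery cohort of 60 BD+cancer probands, 80 BD-only probands and 40
# healthy family controls (parents/siblings sharing ~50% of their
# proband's background carriers), and an independent 25/15 validation
# cohort. Thirty case-exclusive signal variants (10 per region stratum,
# each carried by 3-6 unrelated cases) are planted among 2,000
# background variants with carrier frequencies log-uniform on
# [0.005, 0.2]. All downstream stages read only the files written here.

suppressMessages(library(bdvoi))

seed <- 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)
gff <- file.path(out, "genes.gff3")
simulate_gene_model(cfg, gff)
model <- load_gene_model(gff)
message("gene model: ", nrow(model$genes), " genes (",
        sum(model$genes$biotype == "ncRNA"), " ncRNA) on ", cfg$contig)

disc <- simulate_cohort(cfg, model, out)
val <- simulate_validation(cfg, disc$truth, out)
shp <- cohort_shape(cfg)
message("discovery cohort: ", shp$n_case, " case / ", shp$n_bd_only,
        " BD-only / ", shp$n_control, " control samples (",
        shp$n_total, " total)")
message("validation cohort: ", shp$n_val_case, " case / ",
        shp$n_val_bd_only, " BD-only")
message("planted signal: ", nrow(disc$truth$signal), " variants; truth in ",
        disc$truth_path)
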