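small_cfg <- function(...) {
  sim_config(n_case = 15L, n_bd_only = 15L, n_control = 8L, n_genes = 12L,
             contig_length = 60000L, n_background = 120L,
             n_signal = c(coding = 3L, noncoding = 3L, intergenic = 3L), ...)
}

sim_all <- function(cfg, dir) {
  gff <- file.path(dir, "genes.gff3")
  simulate_gene_model(cfg, gff)
  model <- load_gene_model(gff)
  disc <- simulate_cohort(cfg, model, dir)
  list(model = model, disc = disc, gff = gff)
}

test_that("simulated gene models honor their configuration", {
  d <- withr::local_tempdir()
  cfg2 <- sim_config(n_genes = 2L, contig_length = 10000L, seed = 3)
  simulate_gene_model(cfg2, file.path(d, "two.gff3"))
  m2 <- load_gene_model(file.path(d, "two.gff3"))
  expect_equal(nrow(m2$genes), 2L)
  expect_lt(m2$genes$end[1], m2$genes$start[2] + 1L)  # disjoint spans
  cfg_nc <- sim_config(n_genes = 6L, contig_length = 30000L,
                       ncrna_fraction = 1, seed = 4)
  simulate_gene_model(cfg_nc, file.path(d, "nc.gff3"))
  mnc <- load_gene_model(file.path(d, "nc.gff3"))
  expect_true(all(mnc$genes$biotype == "ncRNA"))
  expect_equal(sum(mnc$parts$type == "cds"), 0L)
  expect_error(simulate_gene_model(sim_config(n_genes = 100L,
                                              contig_length = 5000L),
                                   file.path(d, "x.gff3")),
               "too short")
})

test_that("the full simulated triple is byte-identical for a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- small_cfg(seed = 21)
  s1 <- sim_all(cfg, d1)
  v1 <- simulate_validation(cfg, s1$disc$truth, d1)
  s2 <- sim_all(cfg, d2)
  v2 <- simulate_validation(cfg, s2$disc$truth, d2)
  for (f in c("genes.gff3", "discovery.vcf", "discovery_sheet.tsv",
              "truth.json", "validation.vcf", "validation_sheet.tsv")) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("simulated cohorts satisfy every downstream contract", {
  d <- withr::local_tempdir()
  cfg <- small_cfg(seed = 31)
  s <- sim_all(cfg, d)
  co <- read_cohort(s$disc$vcf, s$disc$sheet)  # validates sheet + matrix
  expect_s3_class(co$sheet, "sample_sheet")
  expect_true(all(co$matrix$carrier %in% c(0L, 1L)))
  sel <- annotate_selection(select_variants(co$matrix, co$sheet), s$model)
  # every planted signal variant passes the filter (recall 1 by construction)
  sig_ids <- variant_key_id(s$disc$truth$signal)
  expect_true(all(sig_ids %in% variant_key_id(sel)))
  # and lands in its designed stratum
  sel_ids <- variant_key_id(sel)
  expect_equal(sel$stratum[match(sig_ids, sel_ids)],
               s$disc$truth$signal$stratum)
  # exclusivity: zero carriers among BD-only and controls
  excl <- co$sheet$sample_id[co$sheet$group %in% c("BD_ONLY", "CONTROL")]
  expect_equal(sum(co$matrix$carrier[excl, sel_ids]), 0L)
})

test_that("adversarial decoys with a BD-only carrier are filtered out", {
  d <- withr::local_tempdir()
  cfg <- small_cfg(seed = 41, n_adversarial = 4L)
  s <- sim_all(cfg, d)
  co <- read_cohort(s$disc$vcf, s$disc$sheet)
  sel <- select_variants(co$matrix, co$sheet)
  dec_ids <- variant_key_id(s$disc$truth$decoys)
  expect_equal(sum(dec_ids %in% variant_key_id(sel)), 0L)
  # the decoys do recur in enough cases; only exclusivity removes them
  cases <- co$sheet$sample_id[co$sheet$group == "BD_CANCER"]
  expect_true(all(colSums(co$matrix$carrier[cases, dec_ids]) >= 3L))
})

test_that("validation replant rate controls case signal load", {
  d <- withr::local_tempdir()
  cfg0 <- small_cfg(seed = 51, replant_rate = 0)
  s <- sim_all(cfg0, d)
  sig_ids <- variant_key_id(s$disc$truth$signal)
  val0 <- simulate_validation(cfg0, s$disc$truth, d)
  v0 <- read_cohort(val0$vcf, val0$sheet)
  expect_equal(sum(v0$matrix$carrier[, sig_ids]), 0L)  # no signal replanted
  cfg1 <- small_cfg(seed = 51, replant_rate = 1)
  val1 <- simulate_validation(cfg1, s$disc$truth, d)
  v1 <- read_cohort(val1$vcf, val1$sheet)
  cases <- v1$sheet$sample_id[v1$sheet$group == "BD_CANCER"]
  others <- setdiff(v1$sheet$sample_id, cases)
  # every validation case carries every signal variant; BD-only none
  expect_true(all(v1$matrix$carrier[cases, sig_ids] == 1L))
  expect_equal(sum(v1$matrix$carrier[others, sig_ids]), 0L)
  # default sizes mirror the validation design: 40 samples, 25 cancer
  shp <- cohort_shape(sim_config())
  expect_equal(shp$n_val_total, 40L)
  expect_equal(shp$n_val_case, 25L)
})

test_that("null simulations match the closed-form spurious-pass expectation", {
  # no planted signal: every selection is a false positive whose
  # probability has a closed binomial form
  obs <- 0; expc <- 0; varc <- 0
  for (seed in 1:12) {
    d <- withr::local_tempdir()
    cfg <- sim_config(n_case = 12L, n_bd_only = 12L, n_control = 6L,
                      n_genes = 8L, contig_length = 40000L,
                      n_background = 100L, freq_range = c(0.05, 0.3),
                      n_signal = c(coding = 0L, noncoding = 0L,
                                   intergenic = 0L),
                      seed = 60 + seed)
    s <- sim_all(cfg, d)
    co <- read_cohort(s$disc$vcf, s$disc$sheet)
    sel <- select_variants(co$matrix, co$sheet)
    e <- expected_spurious_selections(
      s$disc$truth$freqs, cfg$n_case, cfg$n_bd_only,
      s$disc$truth$n_case_with_control, s$disc$truth$n_bd_with_control)
    obs <- obs + nrow(sel); expc <- expc + e$expected; varc <- varc + e$variance
  }
  expect_lt(abs(obs - expc), 3 * sqrt(varc))
})
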