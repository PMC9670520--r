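# annotated selection over the toy model, constructed directly:
# variants in the noncoding stratum mapped to known genes
toy_selection <- function(pos1, genes, stratum = "noncoding") {
  sel <- data.frame(contig = "chr1", pos1 = pos1, ref = "A", alt = "T",
                    case_carriers = 3L, stratum = stratum,
                    stringsAsFactors = FALSE)
  sel$genes <- genes
  sel$gene_ids <- vapply(genes, paste, character(1), collapse = ",")
  class(sel) <- c("selection", "data.frame")
  sel
}

test_that("mutation loads count carried selected variants per gene", {
  ids <- c("C1", "C2", "C3", "B1")
  sheet <- make_sheet(ids, c(rep("BD_CANCER", 3), "BD_ONLY"))
  sel <- toy_selection(c(400L, 450L, 2200L),
                       list("GA", "GA", c("GA", "GB")))
  carrier <- matrix(c(1, 1, 0, 0,   # v@400 (GA)
                      1, 0, 0, 0,   # v@450 (GA)
                      1, 0, 1, 0),  # v@2200 (GA+GB, 2-gene)
                    4, 3, dimnames = list(ids, NULL))
  cm <- make_cm(carrier, data.frame(contig = "chr1",
                                    pos1 = c(400L, 450L, 2200L),
                                    ref = "A", alt = "T"))
  fm <- build_feature_matrix(sel, cm, sheet, "noncoding")
  # C1 carries 3 variants hitting GA -> load 3; the 2-gene variant adds
  # +1 to both GA and GB columns for each carrier (hand count)
  expect_equal(fm$genes, c("GA", "GB"))
  expect_equal(unname(fm$load[, "GA"]), c(3L, 1L, 1L, 0L))
  expect_equal(unname(fm$load[, "GB"]), c(1L, 0L, 1L, 0L))
  expect_equal(fm$labels, c(1L, 1L, 1L, 0L))
  # column-sum identity over case samples, brute-forced by incidence
  case_load <- colSums(fm$load[fm$labels == 1L, ])
  manual <- c(GA = sum(carrier[1:3, c(1, 2, 3)]), GB = sum(carrier[1:3, 3]))
  expect_equal(case_load, manual)
  # first-gene-only mode credits GA alone
  fm1 <- build_feature_matrix(sel, cm, sheet, "noncoding", first_gene_only = TRUE)
  expect_equal(fm1$genes, "GA")
  # binarized loads are presence/absence
  fmb <- build_feature_matrix(sel, cm, sheet, "noncoding", binarize = TRUE)
  expect_true(all(fmb$load %in% c(0L, 1L)))
  # an empty stratum yields an empty matrix, not an error
  fme <- build_feature_matrix(sel, cm, sheet, "coding")
  expect_equal(length(fme$genes), 0L)
})

test_that("a fixed gene order conforms validation features to discovery columns", {
  ids <- c("V1", "V2")
  sheet <- make_sheet(ids, c("BD_CANCER", "BD_ONLY"))
  sel <- toy_selection(400L, list("GA"))
  cm <- make_cm(matrix(c(1, 0), 2, 1, dimnames = list(ids, NULL)),
                data.frame(contig = "chr1", pos1 = 400L, ref = "A", alt = "T"))
  fm <- build_feature_matrix(sel, cm, sheet, "noncoding",
                             genes = c("GA", "GB", "GZ"))
  expect_equal(fm$genes, c("GA", "GB", "GZ"))
  expect_equal(unname(fm$load[, "GZ"]), c(0L, 0L))  # absent gene -> zero column
})

simulate_signal_fm <- function(seed, n = 200, n_noise = 50) {
  # one informative gene among noise: cases tend to carry load there
  set.seed(seed)
  labels <- rep(c(1L, 0L), each = n / 2)
  load <- matrix(rpois(n * (n_noise + 1), 0.3), n, n_noise + 1)
  load[labels == 1L, 1] <- load[labels == 1L, 1] + rpois(n / 2, 2)
  colnames(load) <- c("SIGNAL", sprintf("N%02d", seq_len(n_noise)))
  structure(list(stratum = "coding", genes = colnames(load),
                 samples = sprintf("S%03d", seq_len(n)), load = load,
                 labels = labels), class = "feature_matrix")
}

test_that("random-forest importances sum to one and retain the informative gene", {
  for (seed in 1:10) {
    fm <- simulate_signal_fm(seed)
    rep <- importance_filter(fm, threshold = 1e-5, seed = seed)
    expect_equal(sum(rep$importance), 1)
    expect_true(all(rep$importance >= 0))
    expect_true("SIGNAL" %in% rep$kept_genes, label = paste("seed", seed))
  }
  # threshold zero drops nothing
  fm <- simulate_signal_fm(1)
  expect_equal(importance_filter(fm, threshold = 0)$kept_genes, fm$genes)
  # single-class labels are rejected
  fm$labels <- rep(1L, length(fm$labels))
  expect_error(importance_filter(fm), "both classes")
})

test_that("forward selection picks the informative gene first and stays within survivors", {
  first_picks <- vapply(1:10, function(seed) {
    fm <- simulate_signal_fm(seed, n = 120, n_noise = 8)
    ffs <- forward_select(fm, cv_folds = 3, seed = seed)
    expect_true(all(ffs$kept_genes %in% fm$genes))
    ffs$kept_genes[1]
  }, character(1))
  expect_gt(mean(first_picks == "SIGNAL"), 0.5)  # majority of seeds
})

test_that("forward selection stopping rule honors patience", {
  # constant features: every candidate scores exactly the trivial 0.5,
  # so with patience 0 the search returns only the best single gene
  fm <- structure(list(stratum = "coding", genes = c("A", "B", "C"),
                       samples = sprintf("S%02d", 1:40),
                       load = matrix(0L, 40, 3,
                                     dimnames = list(NULL, c("A", "B", "C"))),
                       labels = rep(c(1L, 0L), 20)),
                  class = "feature_matrix")
  ffs <- forward_select(fm, cv_folds = 4, patience = 0, seed = 7)
  expect_equal(length(ffs$kept_genes), 1L)
  expect_error(forward_select(fm, cv_folds = 25, seed = 1), "exceeds")
})

test_that("reduction is reproducible for a fixed seed", {
  fm <- simulate_signal_fm(5, n = 80, n_noise = 6)
  a <- importance_filter(fm, seed = 42)
  b <- importance_filter(fm, seed = 42)
  expect_identical(a, b)
  fa <- forward_select(fm, cv_folds = 4, seed = 42)
  fb <- forward_select(fm, cv_folds = 4, seed = 42)
  expect_identical(fa, fb)
})

test_that("reduction summary recounts surviving variants", {
  sel <- toy_selection(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10) * 100L,
                       list("G1", "G1", c("G1", "G2"), "G2", "G3",
                            "G3", c("G3", "G4"), "G4", "G4", "G4"))
  all_kept <- reduction_summary(sel, c("G1", "G2", "G3", "G4"))
  expect_equal(all_kept$variants_after, all_kept$variants_before)
  none <- reduction_summary(sel, character(0))
  expect_equal(none$variants_after, 0L)
  # drop G3, G4: brute-force recount of variant -> gene incidence
  kept <- reduction_summary(sel, c("G1", "G2"))
  manual <- sum(vapply(sel$genes, function(g) any(g %in% c("G1", "G2")),
                       logical(1)))
  expect_equal(kept$variants_after, manual)
  expect_equal(manual, 4L)
  expect_equal(kept$pct_reduction, 60)
})
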