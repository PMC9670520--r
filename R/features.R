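#' Build a gene-level mutation-load feature matrix for one stratum
#'
#' Collapses the selected variants of one region stratum to per-gene
#' counts ("weights"): `load[s, g]` is the number of selected variants
#' mapped to gene `g` that proband `s` carries. A variant mapped to k
#' genes contributes one count to each of the k columns (use
#' `first_gene_only = TRUE` to credit only the alphabetically first
#' gene). Counts are computed over probands only; labels are 1 for
#' BD+cancer and 0 for BD-only.
#'
#' @param sel An annotated `selection` (see [annotate_selection()]).
#' @param cm A `carrier_matrix` holding genotypes for the samples to score
#'   (discovery or validation cohort).
#' @param sheet The matching `sample_sheet`.
#' @param stratum One of `"coding"`, `"noncoding"`, `"intergenic"`.
#' @param genes Optional fixed gene order (e.g. the discovery gene set
#'   when scoring a validation cohort); genes with no variants present
#'   become all-zero columns. When `NULL`, all mapped genes are used and
#'   all-zero columns are dropped.
#' @param binarize Reduce loads to presence/absence (default `FALSE`:
#'   raw integer counts).
#' @param first_gene_only Credit multi-gene variants to their first
#'   mapped gene only (default `FALSE`).
#' @return A `feature_matrix`: list with `stratum`, `genes`, `samples`,
#'   `load` (samples x genes integer matrix) and `labels`.
#' @export
build_feature_matrix <- function(sel, cm, sheet, stratum,
                                 genes = NULL, binarize = FALSE,
                                 first_gene_only = FALSE) {
  stopifnot(stratum %in% c("coding", "noncoding", "intergenic"))
  sheet <- sheet[match(cm$samples, sheet$sample_id), , drop = FALSE]
  keep_s <- sheet$role == "proband" & sheet$group %in% c("BD_CANCER", "BD_ONLY")
  samples <- sheet$sample_id[keep_s]
  labels <- as.integer(sheet$group[keep_s] == "BD_CANCER")
  sub <- sel[sel$stratum == stratum, , drop = FALSE]
  ids <- variant_key_id(sub)
  present <- ids %in% colnames(cm$carrier)
  sub <- sub[present, , drop = FALSE]
  ids <- ids[present]
  gene_lists <- sub$genes
  if (first_gene_only) gene_lists <- lapply(gene_lists, `[`, 1L)
  all_genes <- sort(unique(unlist(gene_lists)))
  if (!is.null(genes)) all_genes <- genes
  if (!length(all_genes) || !length(ids)) {
    load <- matrix(0L, length(samples), length(all_genes),
                   dimnames = list(samples, all_genes))
    return(structure(list(stratum = stratum, genes = all_genes, samples = samples,
                          load = load, labels = labels),
                     class = "feature_matrix"))
  }
  # variant x gene incidence
  inc <- matrix(0L, length(ids), length(all_genes), dimnames = list(ids, all_genes))
  for (i in seq_along(ids)) {
    g <- intersect(gene_lists[[i]], all_genes)
    inc[i, g] <- 1L
  }
  load <- cm$carrier[samples, ids, drop = FALSE] %*% inc
  if (binarize) load <- (load > 0L) * 1L
  storage.mode(load) <- "integer"
  if (is.null(genes)) {
    nz <- colSums(load) > 0L
    load <- load[, nz, drop = FALSE]
    all_genes <- all_genes[nz]
  }
  structure(list(stratum = stratum, genes = all_genes, samples = samples,
                 load = load, labels = labels),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("feature_matrix [", x$stratum, "]: ", length(x$samples), " samples x ",
      length(x$genes), " genes; ", sum(x$labels), " cases\n", sep = "")
  invisible(x)
}

#' Drop genes below a random-forest importance threshold
#'
#' First reduction layer: fits an impurity-based random forest of
#' `n_trees` decision trees on (load, labels), rescales the per-gene
#' importances so they sum to 1, and drops every gene with relative
#' importance below `threshold`.
#'
#' @param fm A `feature_matrix` with both classes present.
#' @param threshold Relative-importance cutoff (default `1e-5`).
#' @param n_trees Number of trees (default 200).
#' @param seed RNG seed; results are reproducible given the seed.
#' @return list with `kept_genes`, `dropped_by_importance` and the
#'   normalized `importance` vector.
#' @export
importance_filter <- function(fm, threshold = 1e-5, n_trees = 200L, seed = 1L) {
  if (length(unique(fm$labels)) < 2L) {
    stop("importance_filter needs both classes present in labels")
  }
  if (!length(fm$genes)) {
    return(list(kept_genes = character(0), dropped_by_importance = character(0),
                importance = numeric(0)))
  }
  x <- as.data.frame(fm$load)
  names(x) <- fm$genes
  fit <- ranger::ranger(x = x, y = factor(fm$labels, levels = c(0, 1)),
                        num.trees = n_trees, importance = "impurity",
                        seed = seed, num.threads = 1L)
  imp <- fit$variable.importance[fm$genes]
  imp[imp < 0] <- 0
  tot <- sum(imp)
  if (tot == 0) {
    warning("all importances are zero; no gene separates the classes")
    rel <- imp  # all zero -> everything falls below any positive threshold
  } else {
    rel <- imp / tot
  }
  kept <- fm$genes[rel >= threshold]
  list(kept_genes = kept,
       dropped_by_importance = setdiff(fm$genes, kept),
       importance = rel)
}

# stratified k-fold assignment, deterministic given seed
stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

balanced_accuracy <- function(truth, pred) {
  sens <- if (any(truth == 1L)) mean(pred[truth == 1L] == 1L) else NA_real_
  spec <- if (any(truth == 0L)) mean(pred[truth == 0L] == 0L) else NA_real_
  mean(c(sens, spec), na.rm = TRUE)
}

# cross-validated balanced accuracy of a small random forest on a gene subset
cv_rf_score <- function(load, labels, genes, folds, n_trees, seed) {
  preds <- integer(length(labels))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    if (length(unique(labels[tr])) < 2L) return(NA_real_)
    x <- as.data.frame(load[, genes, drop = FALSE])
    fit <- ranger::ranger(x = x[tr, , drop = FALSE],
                          y = factor(labels[tr], levels = c(0, 1)),
                          num.trees = n_trees, seed = seed, num.threads = 1L)
    preds[!tr] <- as.integer(as.character(
      stats::predict(fit, x[!tr, , drop = FALSE], num.threads = 1L)$predictions))
  }
  balanced_accuracy(labels, preds)
}

#' Greedy forward feature selection
#'
#' Second reduction layer: starting from the empty set, repeatedly adds
#' the gene that maximizes cross-validated balanced accuracy of a
#' random-forest scorer. When the best candidate fails to improve the
#' running best score for `patience` consecutive rounds the search
#' stops and the best-scoring prefix is returned.
#'
#' @param fm A `feature_matrix`.
#' @param genes Candidate genes (typically `kept_genes` from
#'   [importance_filter()]).
#' @param cv_folds Number of stratified CV folds (default 5).
#' @param patience Consecutive non-improving rounds tolerated before
#'   stopping (default 1).
#' @param n_trees Trees in the scoring forest (default 100).
#' @param seed RNG seed.
#' @return list with `kept_genes` (in pick order), `dropped_by_ffs`,
#'   and `score` (the best cross-validated balanced accuracy).
#' @export
forward_select <- function(fm, genes = fm$genes, cv_folds = 5L, patience = 1L,
                           n_trees = 100L, seed = 1L) {
  if (length(genes) < 1L) {
    return(list(kept_genes = character(0), dropped_by_ffs = character(0),
                score = NA_real_))
  }
  min_class <- min(table(fm$labels))
  if (cv_folds > min_class) {
    stop("cv_folds (", cv_folds, ") exceeds the smaller class count (", min_class, ")")
  }
  folds <- stratified_folds(fm$labels, cv_folds, seed)
  chosen <- character(0)
  best_score <- 0.5  # balanced accuracy of a trivial classifier
  best_len <- 0L
  stale <- 0L
  remaining <- genes
  eps <- 1e-9
  while (length(remaining)) {
    cand_scores <- vapply(remaining, function(g) {
      cv_rf_score(fm$load, fm$labels, c(chosen, g), folds, n_trees, seed)
    }, numeric(1))
    if (all(is.na(cand_scores))) break
    best_g <- remaining[which.max(cand_scores)]
    sc <- max(cand_scores, na.rm = TRUE)
    chosen <- c(chosen, best_g)
    remaining <- setdiff(remaining, best_g)
    if (sc > best_score + eps) {
      best_score <- sc
      best_len <- length(chosen)
      stale <- 0L
    } else {
      # the first pick is always retained: it is the best single gene
      if (length(chosen) == 1L) {
        best_len <- 1L
        best_score <- max(best_score, sc)
      }
      stale <- stale + 1L
      if (stale > patience) break
    }
  }
  kept <- chosen[seq_len(best_len)]
  list(kept_genes = kept, dropped_by_ffs = setdiff(genes, kept), score = best_score)
}

#' Summarize the two-layer feature reduction
#'
#' Reports how many selected variants survive when the analysis is
#' restricted to the kept genes: a variant survives when its mapped
#' gene list intersects `kept_genes`.
#'
#' @param sel An annotated `selection`.
#' @param kept_genes Character vector of retained genes.
#' @return list with `variants_before`, `variants_after` and
#'   `pct_reduction`.
#' @export
reduction_summary <- function(sel, kept_genes) {
  before <- nrow(sel)
  after <- if (before) sum(vapply(sel$genes, function(g) any(g %in% kept_genes),
                                  logical(1))) else 0L
  list(variants_before = before, variants_after = after,
       pct_reduction = if (before) 100 * (before - after) / before else 0)
}

#' Run both reduction layers on one stratum
#'
#' Convenience wrapper: [importance_filter()] followed by
#' [forward_select()] on the survivors.
#'
#' @inheritParams importance_filter
#' @inheritParams forward_select
#' @param importance_threshold passed to [importance_filter()].
#' @return A reduction report list combining both layers.
#' @export
reduce_features <- function(fm, importance_threshold = 1e-5, n_trees = 200L,
                            cv_folds = 5L, patience = 1L, seed = 1L) {
  imp <- importance_filter(fm, threshold = importance_threshold,
                           n_trees = n_trees, seed = seed)
  if (length(imp$kept_genes) < 2L) {
    return(c(imp, list(kept_genes_final = imp$kept_genes,
                       dropped_by_ffs = character(0), score = NA_real_)))
  }
  ffs <- forward_select(fm, genes = imp$kept_genes, cv_folds = cv_folds,
                        patience = patience, seed = seed)
  list(kept_genes = imp$kept_genes,
       dropped_by_importance = imp$dropped_by_importance,
       importance = imp$importance,
       kept_genes_final = ffs$kept_genes,
       dropped_by_ffs = ffs$dropped_by_ffs,
       score = ffs$score)
}
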