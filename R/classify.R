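#' Define the MLP hyperparameter search space
#'
#' Ranges cover the knobs usually tuned for a small MLP classifier:
#' iteration cap, L2 `alpha` (log scale), activation, solver, learning
#' rate (log scale) and its schedule, hidden-layer count and neurons
#' per layer. `budget` is the total number of configurations evaluated
#' by the sequential optimizer.
#'
#' @param max_iter length-2 integer range.
#' @param alpha length-2 range, sampled log-uniformly.
#' @param activation subset of `c("relu","tanh","logistic")`.
#' @param solver subset of `c("adam","sgd")`.
#' @param learning_rate length-2 range, sampled log-uniformly.
#' @param lr_schedule subset of `c("constant","adaptive")`.
#' @param hidden_layers length-2 integer range.
#' @param neurons length-2 integer range (per layer).
#' @param budget number of evaluations (>= 1).
#' @param cv_folds folds for the tuning cross-validation.
#' @param seed RNG seed for the whole search.
#' @return A `tuning_space` list.
#' @export
tuning_space <- function(max_iter = c(100L, 400L), alpha = c(1e-5, 1e-1),
                         activation = c("relu", "tanh", "logistic"),
                         solver = c("adam", "sgd"),
                         learning_rate = c(1e-3, 1e-1),
                         lr_schedule = c("constant", "adaptive"),
                         hidden_layers = c(1L, 3L), neurons = c(4L, 32L),
                         budget = 12L, cv_folds = 3L, seed = 1L) {
  sp <- list(max_iter = max_iter, alpha = alpha, activation = activation,
             solver = solver, learning_rate = learning_rate,
             lr_schedule = lr_schedule, hidden_layers = hidden_layers,
             neurons = neurons, budget = as.integer(budget),
             cv_folds = as.integer(cv_folds), seed = as.integer(seed))
  if (sp$budget < 1L) stop("budget must be >= 1")
  lens <- vapply(sp[c("max_iter", "alpha", "learning_rate", "hidden_layers",
                      "neurons")], length, integer(1))
  if (any(lens != 2L)) stop("numeric ranges must have length 2")
  if (!length(sp$activation) || !length(sp$solver) || !length(sp$lr_schedule)) {
    stop("categorical sets must be non-empty")
  }
  class(sp) <- "tuning_space"
  sp
}

sample_mlp_config <- function(space) {
  runif_log <- function(r) exp(stats::runif(1, log(r[1]), log(r[2])))
  list(
    max_iter = as.integer(round(stats::runif(1, space$max_iter[1], space$max_iter[2]))),
    alpha = runif_log(space$alpha),
    activation = sample(space$activation, 1L),
    solver = sample(space$solver, 1L),
    learning_rate = runif_log(space$learning_rate),
    lr_schedule = sample(space$lr_schedule, 1L),
    hidden_layers = sample(seq(space$hidden_layers[1], space$hidden_layers[2]), 1L),
    neurons = as.integer(round(stats::runif(1, space$neurons[1], space$neurons[2])))
  )
}

# encode a configuration as a numeric vector in [0,1]^d for the GP
encode_mlp_config <- function(cfg, space) {
  unit <- function(v, r) if (r[2] > r[1]) (v - r[1]) / (r[2] - r[1]) else 0.5
  unit_log <- function(v, r) unit(log(v), log(r))
  onehot <- function(v, set) as.numeric(set == v)
  c(unit(cfg$max_iter, space$max_iter),
    unit_log(cfg$alpha, space$alpha),
    unit_log(cfg$learning_rate, space$learning_rate),
    unit(cfg$hidden_layers, space$hidden_layers),
    unit(cfg$neurons, space$neurons),
    onehot(cfg$activation, space$activation),
    onehot(cfg$solver, space$solver),
    onehot(cfg$lr_schedule, space$lr_schedule))
}

# zero-mean GP with RBF kernel on [0,1]^d; returns posterior mean/sd
gp_posterior <- function(X, y, Xnew, lengthscale = NULL, nugget = 1e-6) {
  mu <- mean(y)
  sdv <- stats::sd(y)
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  ys <- (y - mu) / sdv
  if (is.null(lengthscale)) lengthscale <- 0.5 * sqrt(ncol(X))
  k <- function(A, B) {
    d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
    exp(-pmax(d2, 0) / (2 * lengthscale^2))
  }
  K <- k(X, X) + diag(nugget + 1e-8, nrow(X))
  Kin <- solve(K)
  Ks <- k(Xnew, X)
  pm <- as.numeric(Ks %*% Kin %*% ys)
  pv <- pmax(1 - rowSums((Ks %*% Kin) * Ks), 1e-12)
  list(mean = pm * sdv + mu, sd = sqrt(pv) * sdv)
}

# weighted cross-validated log-loss of one MLP configuration
cv_logloss <- function(fm, cfg, cv_folds, seed) {
  folds <- stratified_folds(fm$labels, cv_folds, seed)
  y <- fm$labels
  n <- length(y)
  w <- n / (2 * pmax(table(factor(y, levels = c(0, 1))), 1L))
  w <- as.numeric(w[as.character(y)])
  p <- numeric(n)
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- mlp_fit(fm$load[tr, , drop = FALSE], y[tr],
                   hidden = rep(cfg$neurons, cfg$hidden_layers),
                   activation = cfg$activation, alpha = cfg$alpha,
                   solver = cfg$solver, learning_rate = cfg$learning_rate,
                   lr_schedule = cfg$lr_schedule, max_iter = cfg$max_iter,
                   seed = seed + f)
    p[!tr] <- predict(fit, fm$load[!tr, , drop = FALSE], type = "prob")
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(w * -(y * log(p) + (1 - y) * log(1 - p))) / sum(w)
}

#' Tune and train a per-stratum MLP classifier
#'
#' Sequential model-based minimization of cross-validated class-weighted
#' log-loss: an initial random design, then a Gaussian-process surrogate
#' with expected-improvement acquisition proposes the remaining
#' configurations until `budget` evaluations are spent. The best
#' configuration is refit on the full feature matrix. Trials whose loss
#' is non-finite are recorded as failures and the search continues.
#'
#' @param fm A `feature_matrix` with both classes, features already reduced.
#' @param space A [tuning_space()].
#' @return list with `model` (a `bdvoi_mlp`), `best_params`, and a
#'   `trials` data.frame (one row per evaluation).
#' @export
tune_and_train <- function(fm, space = tuning_space()) {
  if (length(unique(fm$labels)) < 2L) stop("feature matrix must contain both classes")
  if (space$budget < 1L) stop("budget must be >= 1")
  if (!length(fm$genes)) stop("feature matrix has no gene columns")
  set.seed(space$seed)
  n_init <- min(space$budget, max(4L, space$budget %/% 3L))
  configs <- list()
  losses <- numeric(0)
  run_trial <- function(cfg, i) {
    loss <- tryCatch(cv_logloss(fm, cfg, space$cv_folds, space$seed + i),
                     error = function(e) NA_real_)
    if (!is.finite(loss)) NA_real_ else loss
  }
  for (i in seq_len(n_init)) {
    configs[[i]] <- sample_mlp_config(space)
    losses[i] <- run_trial(configs[[i]], i)
  }
  while (length(configs) < space$budget) {
    i <- length(configs) + 1L
    ok <- is.finite(losses)
    if (sum(ok) >= 2L) {
      X <- do.call(rbind, lapply(configs[ok], encode_mlp_config, space = space))
      cand <- replicate(200L, sample_mlp_config(space), simplify = FALSE)
      Xc <- do.call(rbind, lapply(cand, encode_mlp_config, space = space))
      post <- gp_posterior(X, losses[ok], Xc)
      fbest <- min(losses[ok])
      z <- (fbest - post$mean) / post$sd
      ei <- post$sd * (z * stats::pnorm(z) + stats::dnorm(z))
      nxt <- cand[[which.max(ei)]]
    } else {
      nxt <- sample_mlp_config(space)
    }
    configs[[i]] <- nxt
    losses[i] <- run_trial(nxt, i)
  }
  if (!any(is.finite(losses))) stop("every tuning trial failed")
  best_i <- which.min(losses)
  best <- configs[[best_i]]
  model <- mlp_fit(fm$load, fm$labels,
                   hidden = rep(best$neurons, best$hidden_layers),
                   activation = best$activation, alpha = best$alpha,
                   solver = best$solver, learning_rate = best$learning_rate,
                   lr_schedule = best$lr_schedule, max_iter = best$max_iter,
                   seed = space$seed)
  trials <- cbind(do.call(rbind, lapply(configs, as.data.frame)),
                  cv_logloss = losses)
  list(model = model, best_params = best, trials = trials, genes = fm$genes)
}

#' Label a cohort with per-stratum models and combine by majority vote
#'
#' Each stratum model casts one vote per sample; the combined label is
#' the one receiving at least two of the three votes. If a stratum
#' model is missing its vote abstains and the majority degrades to the
#' remaining votes, breaking a 1-1 tie toward label 0.
#'
#' @param models Named list with (some of) `coding`, `noncoding`,
#'   `intergenic`, each a result of [tune_and_train()] (or `NULL`).
#' @param fms Named list of validation `feature_matrix` objects built
#'   with each model's training gene order.
#' @return A `prediction_report`: per-sample votes and majority label,
#'   plus summary accuracies when the feature matrices carry labels.
#' @export
predict_cohort <- function(models, fms) {
  strata <- c("coding", "noncoding", "intergenic")
  avail <- strata[vapply(strata, function(s) !is.null(models[[s]]), logical(1))]
  if (!length(avail)) stop("no stratum model available")
  samples <- fms[[avail[1]]]$samples
  votes <- matrix(NA_integer_, length(samples), 3L,
                  dimnames = list(samples, strata))
  for (s in avail) {
    fm <- fms[[s]]
    stopifnot(identical(fm$samples, samples))
    x <- fm$load[, models[[s]]$genes, drop = FALSE]
    votes[, s] <- predict(models[[s]]$model, x, type = "class")
  }
  n_votes <- rowSums(!is.na(votes))
  ones <- rowSums(votes == 1L, na.rm = TRUE)
  majority <- ifelse(ones * 2L > n_votes, 1L, 0L)  # 1-1 tie falls to 0
  per_sample <- data.frame(sample_id = samples,
                           vote_coding = votes[, "coding"],
                           vote_noncoding = votes[, "noncoding"],
                           vote_intergenic = votes[, "intergenic"],
                           majority_label = as.integer(majority),
                           stringsAsFactors = FALSE)
  truth <- fms[[avail[1]]]$labels
  summary <- NULL
  if (!is.null(truth)) {
    per_sample$true_label <- truth
    acc <- function(pred) mean(pred == truth, na.rm = TRUE)
    stratum_acc <- vapply(strata, function(s)
      if (s %in% avail) acc(votes[, s]) else NA_real_, numeric(1))
    comb <- acc(majority)
    summary <- list(
      stratum_accuracy = stratum_acc,
      stratum_accuracy_pct = round(100 * stratum_acc),
      stratum_correct = vapply(strata, function(s)
        if (s %in% avail) sum(votes[, s] == truth) else NA_integer_, numeric(1)),
      combined_accuracy = comb,
      combined_accuracy_pct = round(100 * comb),
      n = length(truth),
      errors_by_class = c(
        miss_case = sum(majority == 0L & truth == 1L),
        miss_noncancer = sum(majority == 1L & truth == 0L))
    )
  }
  structure(list(per_sample = per_sample, summary = summary),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("prediction_report:", nrow(x$per_sample), "samples\n")
  if (!is.null(x$summary)) {
    s <- x$summary
    cat("  per-stratum correct:",
        paste(names(s$stratum_correct), s$stratum_correct, sep = "=", collapse = " "),
        "of", s$n, "\n")
    cat("  majority vote: ", sum(x$per_sample$majority_label == x$per_sample$true_label),
        "/", s$n, " correct (", s$combined_accuracy_pct, "%, fraction ",
        signif(s$combined_accuracy, 3), ")\n", sep = "")
  }
  invisible(x)
}

#' Compare per-individual mutation loads between groups
#'
#' Counts, for every proband, the selected variants it carries and
#' compares BD+cancer against BD-only with a two-sided Wilcoxon
#' rank-sum test, alongside boxplot-ready five-number summaries.
#'
#' @param sel A `selection` (annotation not required).
#' @param cm A `carrier_matrix` for the cohort to score.
#' @param sheet The matching `sample_sheet`.
#' @return A `load_comparison`, see [compare_load_vectors()].
#' @export
mutation_load_compare <- function(sel, cm, sheet) {
  sheet <- sheet[match(cm$samples, sheet$sample_id), , drop = FALSE]
  ids <- intersect(variant_key_id(sel), colnames(cm$carrier))
  counts <- rowSums(cm$carrier[, ids, drop = FALSE])
  a <- counts[sheet$group == "BD_CANCER" & sheet$role == "proband"]
  b <- counts[sheet$group == "BD_ONLY" & sheet$role == "proband"]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  compare_load_vectors(a, b)
}

#' Wilcoxon rank-sum comparison of two count vectors
#'
#' @param a,b Non-negative count vectors (BD+cancer and BD-only loads).
#' @return A `load_comparison` list: per-group five-number summaries,
#'   medians, IQRs, and the two-sided rank-sum statistic and p-value
#'   (`NA`, with a warning, when a group has fewer than 2 observations).
#' @export
compare_load_vectors <- function(a, b) {
  fv <- function(v) {
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE, type = 7)
    c(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
  }
  out <- list(counts = list(bd_cancer = unname(a), bd_only = unname(b)),
              summary = rbind(bd_cancer = fv(a), bd_only = fv(b)),
              medians = c(bd_cancer = stats::median(a), bd_only = stats::median(b)),
              iqrs = c(bd_cancer = stats::IQR(a), bd_only = stats::IQR(b)),
              statistic = NA_real_, p_value = NA_real_)
  if (length(a) < 2L || length(b) < 2L) {
    warning("group with fewer than 2 observations; rank-sum test skipped")
  } else if (length(unique(c(a, b))) == 1L) {
    out$statistic <- length(a) * length(b) / 2
    out$p_value <- 1  # identical distributions, maximal p
  } else if (choose(length(a) + length(b), length(a)) <= 10000) {
    # small groups: exact permutation distribution of the rank-sum
    # statistic (ties counted 1/2), which wilcox.test cannot provide
    # in the presence of ties
    vals <- c(a, b)
    na <- length(a)
    w_of <- function(idx) {
      x <- vals[idx]; y <- vals[-idx]
      sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    }
    w_all <- apply(utils::combn(length(vals), na), 2L, w_of)
    w_obs <- w_of(seq_len(na))
    out$statistic <- w_obs
    out$p_value <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    out$statistic <- unname(wt$statistic)
    out$p_value <- wt$p.value
  }
  class(out) <- "load_comparison"
  out
}

#' @export
print.load_comparison <- function(x, ...) {
  cat("mutation-load comparison (BD+cancer vs BD-only)\n")
  print(round(x$summary, 2))
  cat("rank-sum W =", x$statistic, ", two-sided p =", signif(x$p_value, 3), "\n")
  invisible(x)
}
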