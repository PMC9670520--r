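# a deterministic one-feature "voter": trained on clearly separated
# loads so its vote on 0 / 10 inputs is fully predictable
make_voter <- function(gene, seed = 1) {
  x <- matrix(rep(c(0, 10), each = 20), ncol = 1, dimnames = list(NULL, gene))
  y <- rep(c(0L, 1L), each = 20)
  fit <- mlp_fit(x, y, hidden = 4L, max_iter = 300L, learning_rate = 0.05,
                 seed = seed)
  list(model = fit, genes = gene)
}

voter_fm <- function(gene, values, labels) {
  structure(list(stratum = "any", genes = gene,
                 samples = sprintf("S%d", seq_along(values)),
                 load = matrix(values, ncol = 1, dimnames = list(NULL, gene)),
                 labels = labels),
            class = "feature_matrix")
}

test_that("MLP training separates a linearly separable toy set", {
  set.seed(1)
  x <- cbind(a = c(rnorm(30, -3), rnorm(30, 3)), b = rnorm(60))
  y <- rep(c(0L, 1L), each = 30)
  for (act in c("relu", "tanh", "logistic")) {
    fit <- mlp_fit(x, y, hidden = c(8, 4), activation = act,
                   learning_rate = 0.05, max_iter = 400, seed = 3)
    expect_equal(mean(predict(fit, x, type = "class") == y), 1,
                 label = paste("activation", act))
  }
  # sgd solver and adaptive schedule also converge on this toy set
  fit <- mlp_fit(x, y, hidden = 8, solver = "sgd", learning_rate = 0.05,
                 lr_schedule = "adaptive", max_iter = 400, seed = 3)
  expect_equal(mean(predict(fit, x, type = "class") == y), 1)
})

test_that("MLP fits are bit-reproducible for a fixed seed", {
  set.seed(2)
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0L, 1L), 20)
  f1 <- mlp_fit(x, y, hidden = c(6, 6), seed = 11)
  f2 <- mlp_fit(x, y, hidden = c(6, 6), seed = 11)
  expect_identical(f1$W, f2$W)
  expect_identical(predict(f1, x), predict(f2, x))
})

test_that("hyperparameter search respects its budget and is seed-deterministic", {
  set.seed(4)
  load <- matrix(c(rpois(60, 0.2), rpois(60, 0.2) + rep(c(0L, 3L), 30)),
                 60, 2, dimnames = list(NULL, c("g1", "g2")))
  fm <- structure(list(stratum = "coding", genes = c("g1", "g2"),
                       samples = sprintf("S%02d", 1:60), load = load,
                       labels = rep(c(0L, 1L), 30)),
                  class = "feature_matrix")
  one <- tune_and_train(fm, tuning_space(budget = 1, seed = 5))
  expect_equal(nrow(one$trials), 1L)  # budget 1: the single sampled config
  a <- tune_and_train(fm, tuning_space(budget = 5, seed = 9))
  b <- tune_and_train(fm, tuning_space(budget = 5, seed = 9))
  expect_identical(a$best_params, b$best_params)
  expect_identical(a$trials$cv_logloss, b$trials$cv_logloss)
  expect_error(tuning_space(budget = 0), "budget")
  fm1 <- fm; fm1$labels <- rep(1L, 60)
  expect_error(tune_and_train(fm1), "both classes")
})

test_that("majority vote combines three stratum votes, falling to 0 on a 2-vote tie", {
  models <- list(coding = make_voter("gc"), noncoding = make_voter("gn"),
                 intergenic = make_voter("gi"))
  truth <- c(1L, 0L, 1L, 0L)
  fms <- list(
    coding = voter_fm("gc", c(10, 0, 10, 0), truth),
    noncoding = voter_fm("gn", c(10, 0, 0, 10), truth),
    intergenic = voter_fm("gi", c(0, 0, 10, 0), truth))
  # per-sample vote patterns: (1,1,0), (0,0,0), (1,0,1), (0,1,0)
  rep3 <- predict_cohort(models, fms)
  expect_equal(rep3$per_sample$majority_label, c(1L, 0L, 1L, 0L))
  # median-vote identity: with 3 votes the majority is the median
  votes <- as.matrix(rep3$per_sample[, c("vote_coding", "vote_noncoding",
                                         "vote_intergenic")])
  expect_equal(rep3$per_sample$majority_label,
               as.integer(apply(votes, 1, median)))
  expect_equal(rep3$summary$combined_accuracy, 1)
  # unanimous votes equal every stratum label
  fms_u <- fms
  fms_u$noncoding$load[, 1] <- fms$coding$load[, 1]
  fms_u$intergenic$load[, 1] <- fms$coding$load[, 1]
  rep_u <- predict_cohort(models, fms_u)
  expect_equal(rep_u$per_sample$majority_label,
               unname(rep_u$per_sample$vote_coding))
  # missing stratum model: 1-1 tie breaks toward label 0
  rep2 <- predict_cohort(models[c("coding", "noncoding")],
                         fms[c("coding", "noncoding")])
  expect_equal(rep2$per_sample$majority_label, c(1L, 0L, 0L, 0L))
  expect_error(predict_cohort(list(), fms), "no stratum model")
})

test_that("combined accuracy is bounded by the vote-overlap enumeration", {
  # three voters correct on 30/31/29 of 40 samples; enumerate every
  # feasible overlap pattern of their error sets to bound the number of
  # majority-correct samples
  errs <- c(10L, 9L, 11L)
  feasible <- c()
  for (x12 in 0:errs[1]) for (x13 in 0:(errs[1] - x12)) {
    for (x23 in 0:min(errs[2] - x12, errs[3] - x13)) {
      # remaining errors hit distinct samples with a single wrong vote
      singles <- sum(errs) - 2 * (x12 + x13 + x23)
      n_wrong <- x12 + x13 + x23           # samples with >= 2 wrong votes
      if (n_wrong + singles <= 40) feasible <- c(feasible, 40L - n_wrong)
    }
  }
  rng <- range(feasible)
  expect_equal(rng, c(25L, 40L))
  expect_true(rng[1] >= 22L && rng[2] <= 40L)  # within the stated bound
})

test_that("mutation-load comparison matches exact rank-sum enumeration", {
  cmp <- compare_load_vectors(c(5, 6, 7), c(0, 0, 1))
  expect_equal(unname(cmp$medians), c(6, 0))
  # exact two-sided p by enumerating all 20 assignments of 6 values to
  # two groups of 3: the observed W (all pairwise wins, 9) is the most
  # extreme in one tail
  vals <- c(5, 6, 7, 0, 0, 1)
  combs <- combn(6, 3)
  w_all <- apply(combs, 2, function(i) {
    a <- vals[i]; b <- vals[-i]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  })
  w_obs <- 9
  p_exact <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
  expect_equal(p_exact, 0.1)
  expect_equal(cmp$p_value, p_exact)
})

test_that("degenerate load comparisons are handled without a test statistic", {
  same <- compare_load_vectors(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$p_value, 1)
  expect_equal(unname(same$medians), c(2, 2))
  expect_warning(small <- compare_load_vectors(5, c(1, 2)), "fewer than 2")
  expect_true(is.na(small$p_value))
})

test_that("mutation_load_compare counts selected variants per proband", {
  ids <- c("C1", "C2", "C3", "B1", "B2")
  sheet <- make_sheet(ids, c(rep("BD_CANCER", 3), rep("BD_ONLY", 2)))
  carrier <- matrix(c(1, 1, 0, 0, 0,
                      1, 0, 1, 0, 0,
                      1, 1, 1, 0, 0), 5, 3, dimnames = list(ids, NULL))
  cm <- make_cm(carrier, make_keys(3))
  sel <- select_variants(cm, sheet, min_cases = 2)
  cmp <- mutation_load_compare(sel, cm, sheet)
  # hand count: C1 carries v1+v2+v3 = 3, C2 carries v1+v3 = 2, C3 v2+v3 = 2
  expect_equal(sort(cmp$counts$bd_cancer), c(2, 2, 3))
  # BD-only probands carry no selected variant on discovery data
  expect_equal(cmp$counts$bd_only, c(0, 0))
  expect_equal(unname(cmp$medians["bd_only"]), 0)
})
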