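# separable two-feature cohort: cases shifted on both informative features
separable_data <- function(seed, n = 40, p_noise = 8, shift = 5) {
  set.seed(seed)
  labels <- rep(c(FALSE, TRUE), each = n / 2)
  x <- matrix(rnorm(n * (2 + p_noise)), n,
              dimnames = list(sprintf("S%02d", 1:n),
                              c("rmsk:AluY", "rmsk:AluSx",
                                paste0("G", seq_len(p_noise)))))
  x[labels, 1:2] <- x[labels, 1:2] + shift
  list(x = x, labels = setNames(labels, rownames(x)))
}

test_that("stratified split preserves class proportions deterministically", {
  labels <- setNames(rep(c("healthy", "disease"), each = 20),
                     sprintf("S%02d", 1:40))
  sp <- stratified_split(labels, train_frac = 0.8, seed = 11)
  expect_length(sp$train, 32)
  expect_length(sp$test, 8)
  expect_equal(sum(labels[sp$train] == "disease"), 16)
  expect_equal(sum(labels[sp$test] == "disease"), 4)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, stratified_split(labels, 0.8, seed = 11))
  sp2 <- stratified_split(labels, 0.8, seed = 12)
  expect_length(sp2$train, 32)
  expect_false(setequal(sp$train, sp2$train) &&
                 identical(sort(sp$train), sort(sp2$train)))
})

test_that("the specificity-anchored threshold maximizes sensitivity", {
  ctrl <- seq(0.05, 0.50, by = 0.05)
  prob <- c(ctrl, 0.6, 0.7)
  labels <- c(rep(FALSE, 10), TRUE, TRUE)
  t90 <- threshold_at_specificity(prob, labels, target = 0.9)
  expect_equal(t90, 0.475)              # midpoint above the 9th ascending prob
  expect_equal(mean(ctrl < t90), 0.9)   # specificity exactly 0.9

  # enumeration: no smaller candidate satisfies the constraint
  cands <- sort(unique(c(0, (ctrl[-1] + ctrl[-10]) / 2, 1)))
  feasible <- cands[vapply(cands, function(t) mean(ctrl < t) >= 0.9, TRUE)]
  expect_equal(t90, min(feasible))

  # all-zero controls: smallest sentinel above 0
  expect_equal(threshold_at_specificity(c(0, 0, 0, 1), c(F, F, F, T), 0.9), 1)
  # target 1.0 sits above every control probability
  t100 <- threshold_at_specificity(prob, labels, target = 1)
  expect_gt(t100, max(ctrl))

  # monotone in the target
  targets <- seq(0.5, 1, by = 0.05)
  ts <- vapply(targets, function(tg)
    threshold_at_specificity(prob, labels, tg), 0)
  expect_true(all(diff(ts) >= 0))

  expect_warning(threshold_at_specificity(c(0.1, 0.9), c(FALSE, TRUE), 0.9),
                 "coarse")
})

test_that("AUC equals the pair-counting oracle and handles ties", {
  expect_equal(auc_score(c(0.1, 0.2, 0.8, 0.9), c(F, F, T, T)), 1)
  set.seed(23)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    prob <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # forces ties
    expect_equal(auc_score(prob, labels), pair_auc(prob, labels))
  }
  # shuffled labels: AUC concentrates around 1/2
  set.seed(29)
  aucs <- replicate(200, {
    auc_score(runif(40), sample(rep(c(TRUE, FALSE), 20)))
  })
  expect_equal(mean(aucs), 0.5, tolerance = 0.02)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  prob <- runif(60)
  labels <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = prob, quiet = TRUE,
    levels = c(FALSE, TRUE), direction = "<"))))
  expect_equal(auc_score(prob, labels), ref, tolerance = 1e-12)
})

test_that("Clopper-Pearson endpoints match the beta-quantile oracle", {
  expect_equal(binomial_ci(10, 10)[["high"]], 1)
  expect_equal(binomial_ci(0, 10)[["low"]], 0)
  ci <- binomial_ci(8, 10)
  expect_equal(unname(ci), c(0.4439, 0.9748), tolerance = 1e-4)
  for (k in c(0, 1, 5, 9, 10)) {
    ref <- binom.test(k, 10)$conf.int
    expect_equal(unname(binomial_ci(k, 10)), as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("separable planted data trains to AUC 1 with planted features", {
  d <- separable_data(seed = 37)
  fit <- cv_train(d$x, d$labels, seed = 37, feature_set = "test")
  expect_equal(fit$train_metrics$auc, 1.0)
  expect_gte(fit$train_metrics$specificity, 0.9)
  expect_true(all(fit$beta[c("rmsk:AluY", "rmsk:AluSx")] != 0))
  # evaluating on the training data reproduces the training metrics
  ev <- evaluate_test(fit, d$x, d$labels)
  expect_equal(ev$sensitivity, fit$train_metrics$sensitivity)
  expect_equal(ev$auc, fit$train_metrics$auc)
})

test_that("model serialization is deterministic and round-trips", {
  d <- separable_data(seed = 41)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  fit1 <- cv_train(d$x, d$labels, seed = 5, feature_set = "det")
  fit2 <- cv_train(d$x, d$labels, seed = 5, feature_set = "det")
  write_model(fit1, f1)
  write_model(fit2, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical given seed

  back <- read_model(f1)
  expect_equal(back$beta, fit1$beta)
  expect_equal(back$threshold_90, fit1$threshold_90)
  expect_equal(predict_prob(back, d$x), predict_prob(fit1, d$x))
})

test_that("an all-zero-coefficient model degrades gracefully", {
  d <- separable_data(seed = 43)
  fit <- cv_train(d$x, d$labels, seed = 43, feature_set = "null")
  fit$beta[] <- 0                      # regularized to the intercept-only limit
  fit$intercept <- -2
  prob <- predict_prob(fit, d$x)
  expect_true(all(abs(prob - prob[1]) < 1e-12))
  thr <- suppressWarnings(threshold_at_specificity(prob, d$labels, 0.9))
  conf <- confusion_at(prob, d$labels, thr)
  expect_equal(conf$sensitivity, 0)    # everything below the threshold
  expect_equal(conf$specificity, 1)
})

test_that("null training data keeps the threshold specificity calibrated", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(40 * 30), 40,
                dimnames = list(sprintf("S%02d", 1:40), paste0("F", 1:30)))
    labels <- setNames(rep(c(FALSE, TRUE), each = 20), rownames(x))
    fit <- cv_train(x, labels, seed = seed, feature_set = "noise",
                    alpha_grid = c(0, 0.5, 1))
    expect_gte(fit$train_metrics$specificity, 0.88)
    expect_lte(fit$train_metrics$specificity, 1.0)
  }
})

test_that("single-class labels and degenerate folds are rejected", {
  d <- separable_data(seed = 47)
  expect_error(cv_train(d$x, rep(TRUE, nrow(d$x)), seed = 1), "one class")
  expect_error(evaluate_test(cv_train(d$x, d$labels, seed = 1),
                             d$x, rep(TRUE, nrow(d$x))), "both classes")
})

test_that("coefficients pair with fold changes for non-zero repeat features", {
  d <- separable_data(seed = 53)
  fit <- cv_train(d$x, d$labels, seed = 53, feature_set = "cmp")
  de <- data.frame(feature = c("rmsk:AluY", "rmsk:AluSx"),
                   log2FoldChange = c(2.1, 1.8), padj = 1e-4,
                   stringsAsFactors = FALSE)
  tab <- coefficient_vs_lfc(fit, de)
  expect_true(all(startsWith(tab$feature, "rmsk:")))
  expect_equal(nrow(tab), sum(fit$beta != 0 &
                                startsWith(names(fit$beta), "rmsk:")))
  expect_gte(attr(tab, "n_nonzero_total"), nrow(tab))
  # concordant planted signal: positive betas with positive fold changes
  expect_true(all(sign(tab$beta) == sign(tab$log2FoldChange)))

  de_miss <- de[1, , drop = FALSE]
  expect_warning(tab2 <- coefficient_vs_lfc(fit, de_miss), "missing")
  expect_true(any(is.na(tab2$log2FoldChange)))
})
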