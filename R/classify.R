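#' Stratified train/test split
#'
#' Splits samples into training and testing subsets, stratified on the
#' class label so that each class contributes the training fraction within
#' one sample of the target. Deterministic given the seed.
#'
#' @param labels Vector of class labels, named by sample id (or unnamed, in
#'   which case integer indices are returned).
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed.
#' @return List with `train` and `test` sample ids (or indices).
#' @export
stratified_split <- function(labels, train_frac = 0.8, seed) {
  stopifnot(train_frac > 0, train_frac < 1, !missing(seed))
  ids <- if (is.null(names(labels))) seq_along(labels) else names(labels)
  set.seed(seed)
  train <- unlist(lapply(unique(labels), function(lv) {
    pool <- ids[labels == lv]
    n_tr <- round(train_frac * length(pool))
    n_tr <- max(1L, min(length(pool) - 1L, n_tr))
    sample(pool, n_tr)
  }), use.names = FALSE)
  list(train = train, test = setdiff(ids, train))
}

#' Probability threshold achieving a target specificity
#'
#' The smallest threshold t such that specificity (fraction of controls
#' with probability below t, i.e. predicted negative) is at least `target`
#' — equivalently, the threshold maximizing sensitivity subject to the
#' specificity constraint. Candidate thresholds are the midpoints between
#' consecutive distinct control probabilities plus the sentinels 0 and 1;
#' samples with probability >= t are called positive.
#'
#' @param prob Predicted probabilities.
#' @param labels Logical/0-1 vector; `TRUE` = case.
#' @param target Target specificity (default 0.90).
#' @return The threshold, a scalar in `[0, 1]`.
#' @export
threshold_at_specificity <- function(prob, labels, target = 0.90) {
  labels <- as.logical(labels)
  ctrl <- prob[!labels]
  stopifnot(length(ctrl) > 0, target >= 0, target <= 1)
  if (length(ctrl) < 10) {
    warning("fewer than 10 controls: a ", round(100 * target),
            "% specificity threshold is coarse-grained")
  }
  u <- sort(unique(ctrl))
  mids <- if (length(u) > 1) (u[-1] + u[-length(u)]) / 2 else numeric(0)
  cands <- sort(unique(c(0, mids, 1)))
  spec <- vapply(cands, function(t) mean(ctrl < t), 0)
  ok <- which(spec >= target)
  if (length(ok) == 0) return(1)
  cands[ok[1]]
}

#' Sensitivity and specificity at a threshold
#' @param prob Predicted probabilities.
#' @param labels Logical/0-1 vector; `TRUE` = case.
#' @param threshold Probability cutoff; `prob >= threshold` is positive.
#' @return List with `sensitivity`, `specificity`, `tp`, `n_case`,
#'   `tn`, `n_control`.
#' @export
confusion_at <- function(prob, labels, threshold) {
  labels <- as.logical(labels)
  pos <- prob >= threshold
  list(sensitivity = mean(pos[labels]),
       specificity = mean(!pos[!labels]),
       tp = sum(pos & labels), n_case = sum(labels),
       tn = sum(!pos & !labels), n_control = sum(!labels))
}

# stratified fold assignment; redraws if any fold ends up empty
stratified_foldid <- function(labels, nfolds) {
  labels <- as.logical(labels)
  foldid <- integer(length(labels))
  for (lv in c(TRUE, FALSE)) {
    idx <- which(labels == lv)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  foldid
}

#' Cross-validated elastic-net diagnostic classifier
#'
#' Trains penalized logistic-regression models over a grid of elastic-net
#' mixing values (alpha = 0 ridge ... 1 lasso), choosing the regularization
#' strength lambda within each alpha by 10-fold cross-validated binomial
#' deviance, refitting each candidate on the full training split, and
#' selecting the final model by training sensitivity at the
#' `target_specificity` probability threshold, ties broken by training AUC,
#' then by smaller alpha. Features are standardized with training means and
#' standard deviations (stored in the fit and re-applied to test data).
#'
#' @param x Training matrix, samples x features (rownames = sample ids).
#' @param labels Logical/0-1 vector; `TRUE` = case. Must contain both
#'   classes.
#' @param alpha_grid Elastic-net mixing grid (default 0, 0.1, ..., 1).
#' @param nfolds CV folds (default 10).
#' @param seed Integer seed controlling fold assignment.
#' @param target_specificity Specificity anchoring the decision threshold
#'   (default 0.90).
#' @param feature_set Name recorded in the fit (provenance).
#' @return A `ModelFit`: list with `alpha`, `lambda`, `beta` (named vector,
#'   all model features), `intercept`, `center`, `scale`, `threshold_90`,
#'   `train_metrics` (sensitivity at threshold, specificity, AUC, binomial
#'   CI on sensitivity), `leaderboard` (one row per alpha), `feature_set`,
#'   `seed`.
#' @export
cv_train <- function(x, labels, alpha_grid = seq(0, 1, by = 0.1),
                     nfolds = 10, seed, target_specificity = 0.90,
                     feature_set = "unnamed") {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2) stop("training labels contain one class")
  stopifnot(is.matrix(x), nrow(x) == length(labels), !missing(seed))

  # training-only standardization; constant features carry no information
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  keep <- which(scl > 0)
  if (length(keep) == 0) stop("all features constant in training data")
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, ctr[keep], "-"),
              2, scl[keep], "/")
  duplicated_single <- FALSE
  if (ncol(xs) == 1) {
    # glmnet needs >= 2 columns; mirror the single feature and fold the
    # two coefficients back together afterwards
    xs <- cbind(xs, xs)
    colnames(xs)[2] <- paste0(colnames(xs)[1], ".mirror")
    duplicated_single <- TRUE
  }

  set.seed(seed)
  foldid <- stratified_foldid(labels, nfolds)
  tries <- 0
  while (any(tabulate(foldid, nfolds) == 0) && tries < 10) {
    foldid <- stratified_foldid(labels, nfolds)
    tries <- tries + 1
  }
  y <- factor(labels, levels = c(FALSE, TRUE))

  cands <- lapply(alpha_grid, function(a) {
    cvfit <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = a,
                               foldid = foldid, standardize = FALSE,
                               type.measure = "deviance")
    lam <- cvfit$lambda.min
    prob <- as.vector(stats::predict(cvfit, newx = xs, s = "lambda.min",
                                     type = "response"))
    thr <- suppressWarnings(
      threshold_at_specificity(prob, labels, target_specificity))
    conf <- confusion_at(prob, labels, thr)
    co <- as.matrix(stats::coef(cvfit, s = "lambda.min"))
    list(alpha = a, lambda = lam, coef = co, prob = prob, threshold = thr,
         sensitivity = conf$sensitivity, specificity = conf$specificity,
         auc = auc_score(prob, labels))
  })

  sens <- vapply(cands, `[[`, 0, "sensitivity")
  aucs <- vapply(cands, `[[`, 0, "auc")
  best <- order(-sens, -aucs, alpha_grid)[1]
  b <- cands[[best]]

  co <- b$coef[, 1]
  intercept <- co[["(Intercept)"]]
  beta_kept <- co[-1]
  if (duplicated_single) {
    beta_kept <- stats::setNames(sum(beta_kept), names(keep)[1])
  }
  beta <- stats::setNames(rep(0, ncol(x)), colnames(x))
  beta[names(beta_kept)] <- beta_kept
  conf <- confusion_at(b$prob, labels, b$threshold)
  ci <- binomial_ci(conf$tp, conf$n_case)
  leaderboard <- data.frame(
    alpha = alpha_grid,
    lambda = vapply(cands, `[[`, 0, "lambda"),
    train_sensitivity = sens,
    train_specificity = vapply(cands, `[[`, 0, "specificity"),
    train_auc = aucs
  )
  structure(list(
    alpha = b$alpha, lambda = b$lambda,
    beta = beta, intercept = intercept,
    center = ctr, scale = scl,
    threshold_90 = b$threshold,
    target_specificity = target_specificity,
    train_metrics = list(sensitivity = conf$sensitivity,
                         specificity = conf$specificity,
                         auc = b$auc,
                         ci_low = ci[["low"]], ci_high = ci[["high"]],
                         n_case = conf$n_case, n_control = conf$n_control),
    leaderboard = leaderboard,
    feature_set = feature_set, seed = seed
  ), class = "ModelFit")
}

#' @export
print.ModelFit <- function(x, ...) {
  cat("ModelFit [", x$feature_set, "]: alpha=", x$alpha,
      ", lambda=", signif(x$lambda, 4),
      ", ", sum(x$beta != 0), "/", length(x$beta), " non-zero features\n",
      "  training sens=", round(x$train_metrics$sensitivity, 3),
      " @ spec=", round(x$train_metrics$specificity, 3),
      ", AUC=", round(x$train_metrics$auc, 3),
      ", threshold=", signif(x$threshold_90, 4), "\n", sep = "")
  invisible(x)
}

#' Predict case probabilities from a fitted model
#' @param fit A `ModelFit`.
#' @param x Matrix samples x features (same feature columns as training).
#' @return Numeric vector of probabilities.
#' @export
predict_prob <- function(fit, x) {
  stopifnot(inherits(fit, "ModelFit"))
  miss <- setdiff(names(fit$beta), colnames(x))
  if (length(miss) > 0) {
    stop("test matrix missing feature(s): ", paste(utils::head(miss, 5),
                                                   collapse = ", "))
  }
  x <- x[, names(fit$beta), drop = FALSE]
  scl <- ifelse(fit$scale > 0, fit$scale, 1)
  xs <- sweep(sweep(x, 2, fit$center, "-"), 2, scl, "/")
  eta <- fit$intercept + as.vector(xs %*% fit$beta)
  1 / (1 + exp(-eta))
}

#' Evaluate a frozen model on held-out data
#'
#' Applies the model's training-derived standardization and its
#' 90%-specificity probability threshold to test samples; reports test
#' sensitivity (with exact binomial CI), specificity and AUC.
#'
#' @param fit A `ModelFit`.
#' @param x Test matrix, samples x features.
#' @param labels Logical/0-1 test labels; both classes required.
#' @return An `EvalResult` list: `sensitivity`, `specificity`, `auc`,
#'   `ci_low`, `ci_high`, `n_case`, `n_control`, `threshold`.
#' @export
evaluate_test <- function(fit, x, labels) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels)) stop("test set must contain both classes")
  prob <- predict_prob(fit, x)
  conf <- confusion_at(prob, labels, fit$threshold_90)
  ci <- binomial_ci(conf$tp, conf$n_case)
  structure(list(sensitivity = conf$sensitivity,
                 specificity = conf$specificity,
                 auc = auc_score(prob, labels),
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 n_case = conf$n_case, n_control = conf$n_control,
                 threshold = fit$threshold_90),
            class = "EvalResult")
}

#' Compare model coefficients with DE log2 fold changes
#'
#' Restricted to repeat-subfamily features with non-zero model
#' coefficients; the total number of non-zero features (of any class) is
#' reported in attribute `n_nonzero_total`.
#'
#' @param fit A `ModelFit`.
#' @param de A `DEResult`.
#' @return `data.frame` with `feature`, `beta`, `log2FoldChange` (NA with a
#'   warning for features missing from the DE table).
#' @export
coefficient_vs_lfc <- function(fit, de) {
  nz <- fit$beta[fit$beta != 0]
  rep_nz <- nz[startsWith(names(nz), "rmsk:")]
  lfc <- de$log2FoldChange[match(names(rep_nz), de$feature)]
  if (anyNA(lfc) && length(rep_nz) > 0) {
    warning(sum(is.na(lfc)), " non-zero repeat feature(s) missing from DE table")
  }
  out <- data.frame(feature = names(rep_nz), beta = unname(rep_nz),
                    log2FoldChange = lfc, stringsAsFactors = FALSE)
  attr(out, "n_nonzero_total") <- length(nz)
  out
}

#' Serialize / deserialize a ModelFit as JSON
#'
#' The JSON holds alpha, lambda, the sparse non-zero coefficient map, the
#' intercept, standardization vectors and the training-derived threshold.
#' Serialization is deterministic: identical fits produce byte-identical
#' files.
#' @param fit A `ModelFit`.
#' @param path Output JSON path.
#' @export
write_model <- function(fit, path) {
  nz <- fit$beta[fit$beta != 0]
  obj <- list(
    feature_set = fit$feature_set,
    alpha = fit$alpha, lambda = fit$lambda,
    intercept = fit$intercept,
    beta = as.list(nz),
    features = names(fit$beta),
    center = as.list(fit$center), scale = as.list(fit$scale),
    threshold_90 = fit$threshold_90,
    target_specificity = fit$target_specificity,
    train_metrics = fit$train_metrics,
    seed = fit$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  beta <- stats::setNames(rep(0, length(obj$features)), obj$features)
  if (length(obj$beta) > 0) beta[names(obj$beta)] <- unlist(obj$beta)
  structure(list(
    alpha = obj$alpha, lambda = obj$lambda,
    beta = beta, intercept = obj$intercept,
    center = unlist(obj$center), scale = unlist(obj$scale),
    threshold_90 = obj$threshold_90,
    target_specificity = obj$target_specificity,
    train_metrics = as.list(obj$train_metrics),
    feature_set = obj$feature_set, seed = obj$seed
  ), class = "ModelFit")
}
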