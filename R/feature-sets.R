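#' Build the eight canonical classifier feature sets
#'
#' Three categories of input matrices feed the diagnostic models:
#' * `total`: all repeat-naive (gene), repeat-aware (gene + subfamily) or
#'   repeat-alone (subfamily) features with normalized counts;
#' * `differential_expression`: the same three views filtered to features
#'   significant (padj < `alpha`) in a DE analysis computed on the training
#'   split only;
#' * `entropy`: per-group Shannon entropy columns (TE clade entropy), alone
#'   or together with the repeat-naive count features.
#'
#' A leakage guard enforces that the supplied DE result was computed on
#' training samples only: its `samples` provenance attribute must be a
#' subset of `train_ids`.
#'
#' @param aware_norm Repeat-aware `CountMatrix` (`normalized` state); gene
#'   rows plus `rmsk:` subfamily rows.
#' @param de_train A `DEResult` computed on the training split of the aware
#'   matrix (carries `attr(, "samples")`).
#' @param train_ids Training sample ids against which DE provenance is
#'   checked.
#' @param entropy_groups Group names available in the entropy table
#'   (default: taken from `attr(de_train, "entropy_groups")` is not
#'   assumed; pass explicitly, e.g. `unique(entropy_tab$group)`).
#' @param alpha DE significance cutoff (default 0.01).
#' @return Named list of eight `FeatureSet` objects (lists with `name`,
#'   `category`, `features`, `provenance`).
#' @export
build_feature_sets <- function(aware_norm, de_train, train_ids,
                               entropy_groups, alpha = 0.01) {
  stopifnot(cm_state(aware_norm) == "normalized")
  de_samples <- attr(de_train, "samples")
  if (is.null(de_samples)) {
    stop("DE result carries no sample provenance; cannot verify ",
         "training-only computation")
  }
  leaked <- setdiff(de_samples, train_ids)
  if (length(leaked) > 0) {
    stop("DE result was computed on non-training sample(s): ",
         paste(utils::head(leaked, 5), collapse = ", "),
         " - refusing to build leakage-prone feature sets")
  }
  all_feats <- rownames(aware_norm)
  is_rep <- startsWith(all_feats, "rmsk:")
  sig <- de_train$feature[!is.na(de_train$padj) & de_train$padj < alpha]
  fs <- function(name, category, features, provenance) {
    list(name = name, category = category, features = features,
         provenance = provenance)
  }
  sets <- list(
    total_naive = fs("total_naive", "total", all_feats[!is_rep],
                     "all gene features"),
    total_aware = fs("total_aware", "total", all_feats,
                     "all gene + subfamily features"),
    total_repeat_alone = fs("total_repeat_alone", "total", all_feats[is_rep],
                            "all subfamily features"),
    de_naive = fs("de_naive", "differential_expression",
                  intersect(sig, all_feats[!is_rep]), "DE on training split"),
    de_aware = fs("de_aware", "differential_expression",
                  intersect(sig, all_feats), "DE on training split"),
    de_repeat_alone = fs("de_repeat_alone", "differential_expression",
                         intersect(sig, all_feats[is_rep]),
                         "DE on training split"),
    entropy_clade = fs("entropy_clade", "entropy",
                       paste0("entropy:", entropy_groups),
                       "per-group Shannon entropy"),
    entropy_clade_naive = fs("entropy_clade_naive", "entropy",
                             c(paste0("entropy:", entropy_groups),
                               all_feats[!is_rep]),
                             "entropy + gene features")
  )
  sets
}

#' Assemble a model input matrix for a feature set
#'
#' Count features come from the normalized matrix (samples x features);
#' `entropy:<group>` features come from the entropy table (undefined
#' entropies are encoded as 0, i.e. a silent group).
#'
#' @param set A `FeatureSet` from [build_feature_sets()].
#' @param norm The normalized `CountMatrix` (features x samples).
#' @param entropy_tab Entropy table from [shannon_entropy()] (needed for
#'   entropy sets).
#' @param sample_ids Samples (columns) to include, in order.
#' @return Matrix samples x features.
#' @export
assemble_features <- function(set, norm, entropy_tab = NULL,
                              sample_ids = colnames(norm)) {
  count_feats <- set$features[!startsWith(set$features, "entropy:")]
  ent_feats <- set$features[startsWith(set$features, "entropy:")]
  parts <- list()
  if (length(count_feats) > 0) {
    miss <- setdiff(count_feats, rownames(norm))
    if (length(miss) > 0) stop("feature(s) absent from matrix: ",
                               paste(utils::head(miss, 5), collapse = ", "))
    parts$counts <- t(as.matrix(norm)[count_feats, sample_ids, drop = FALSE])
  }
  if (length(ent_feats) > 0) {
    stopifnot(!is.null(entropy_tab))
    groups <- sub("^entropy:", "", ent_feats)
    em <- matrix(0, nrow = length(sample_ids), ncol = length(groups),
                 dimnames = list(sample_ids, ent_feats))
    for (k in seq_along(groups)) {
      sel <- entropy_tab$group == groups[k]
      v <- entropy_tab$entropy[sel][match(sample_ids, entropy_tab$sample[sel])]
      v[is.na(v)] <- 0
      em[, k] <- v
    }
    parts$entropy <- em
  }
  do.call(cbind, unname(parts))
}
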