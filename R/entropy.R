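#' Feature-to-group assignment for composition statistics
#'
#' Genes are grouped by their GENCODE biotype, repeat-subfamily features by
#' their repeat superfamily (`repClass`: SINE, LINE, LTR, Simple_repeat,
#' ...). This is the grouping used for entropy and composition fractions.
#'
#' @param catalog A `FeatureCatalog`.
#' @return Named character vector: feature_id -> group.
#' @export
feature_groups <- function(catalog) {
  stopifnot(inherits(catalog, "FeatureCatalog"))
  stats::setNames(catalog$features$group, catalog$features$feature_id)
}

#' Per-sample Shannon entropy of each feature group
#'
#' For each sample and group (biotype or repeat superfamily), the fractional
#' contribution p_i of each group member to the group total is formed and
#' the entropy H = -sum p_i log2(p_i) is computed (zero terms contribute 0).
#' H is in bits: 0 for a single dominant feature, log2(n) for n equally
#' abundant features. Samples in which a group has zero total counts get an
#' `NA` entropy with a warning.
#'
#' @param norm A `CountMatrix` in `normalized` state.
#' @param grouping Named character vector feature_id -> group (see
#'   [feature_groups()]); features absent from it are ignored.
#' @return `data.frame` with columns `sample`, `group`, `entropy`,
#'   `n_nonzero` (group members with positive counts in that sample).
#' @export
shannon_entropy <- function(norm, grouping) {
  stopifnot(cm_state(norm) == "normalized")
  m <- as.matrix(norm)
  grouping <- grouping[names(grouping) %in% rownames(m)]
  groups <- sort(unique(unname(grouping)))
  out <- expand.grid(sample = colnames(m), group = groups,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$entropy <- NA_real_
  out$n_nonzero <- 0L
  for (g in groups) {
    rows <- names(grouping)[grouping == g]
    sub <- m[rows, , drop = FALSE]
    tot <- colSums(sub)
    H <- vapply(seq_len(ncol(sub)), function(j) {
      if (tot[j] <= 0) return(NA_real_)
      p <- sub[, j] / tot[j]
      p <- p[p > 0]
      -sum(p * log2(p))
    }, 0)
    idx <- out$group == g
    out$entropy[idx] <- H[match(out$sample[idx], colnames(m))]
    out$n_nonzero[idx] <- colSums(sub > 0)[match(out$sample[idx], colnames(m))]
  }
  if (anyNA(out$entropy)) {
    warning(sum(is.na(out$entropy)),
            " (sample, group) pair(s) with zero total counts: entropy undefined")
  }
  out
}

#' Per-sample composition fractions by group
#'
#' Fraction of each sample's normalized counts contributed by each group
#' (biotype or repeat superfamily). Fractions sum to 1 per sample over all
#' groups present in the grouping.
#'
#' @inheritParams shannon_entropy
#' @return `data.frame` with columns `sample`, `group`, `fraction`.
#' @export
composition_fractions <- function(norm, grouping) {
  stopifnot(cm_state(norm) == "normalized")
  m <- as.matrix(norm)
  grouping <- grouping[names(grouping) %in% rownames(m)]
  m <- m[names(grouping), , drop = FALSE]
  agg <- rowsum(m, unname(grouping))
  tot <- colSums(agg)
  frac <- sweep(agg, 2, ifelse(tot > 0, tot, 1), "/")
  out <- data.frame(
    sample = rep(colnames(frac), each = nrow(frac)),
    group = rep(rownames(frac), times = ncol(frac)),
    fraction = as.vector(frac),
    stringsAsFactors = FALSE
  )
  out
}

#' Overall repeat fraction per sample
#'
#' Share of normalized counts assigned to repeat-subfamily features, the
#' headline composition statistic contrasting healthy and disease cell-free
#' RNA profiles.
#' @param norm A `CountMatrix` in `normalized` state.
#' @param catalog A `FeatureCatalog` (must contain repeat features).
#' @return Named numeric vector of per-sample fractions in `[0, 1]`.
#' @export
repeat_fraction <- function(norm, catalog) {
  stopifnot(cm_state(norm) == "normalized",
            inherits(catalog, "FeatureCatalog"))
  m <- as.matrix(norm)
  rep_ids <- catalog$features$feature_id[
    catalog$features$feature_class == "repeat_subfamily"]
  rep_ids <- intersect(rep_ids, rownames(m))
  tot <- colSums(m)
  colSums(m[rep_ids, , drop = FALSE]) / ifelse(tot > 0, tot, 1)
}
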