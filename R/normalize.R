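#' Median-of-ratios size factors
#'
#' Per-sample scale factors computed by the median-of-ratios method: for
#' every feature with positive counts in all samples, the ratio of each
#' sample's count to the feature's geometric mean across samples is formed,
#' and the sample's size factor is the median of those ratios. This is the
#' standard between-library normalization for count data, robust to a
#' minority of strongly differential features.
#'
#' @param raw A `CountMatrix` in `raw` state.
#' @return Named numeric vector of positive per-sample size factors.
#' @export
size_factors <- function(raw) {
  stopifnot(cm_state(raw) == "raw", ncol(raw) >= 2)
  m <- as.matrix(raw)
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos)) {
    stop("no feature has positive counts in every sample; ",
         "size factors undefined (consider a pseudo-reference fallback)")
  }
  logm <- log(m[allpos, , drop = FALSE])
  loggeo <- rowMeans(logm)
  sf <- apply(logm, 2, function(col) exp(stats::median(col - loggeo)))
  stopifnot(all(sf > 0))
  sf
}

#' Normalize a raw count matrix by size factors
#'
#' @param raw A `CountMatrix` in `raw` state.
#' @param sf Size factors from [size_factors()] (recomputed if missing).
#' @return A `CountMatrix` in `normalized` state; attribute `size_factors`.
#' @export
normalize_counts <- function(raw, sf = NULL) {
  stopifnot(cm_state(raw) == "raw")
  if (is.null(sf)) sf <- size_factors(raw)
  stopifnot(length(sf) == ncol(raw), all(sf > 0))
  m <- sweep(as.matrix(raw), 2, sf, "/")
  count_matrix(m, state = "normalized", size_factors = sf)
}

#' Log-transform normalized counts
#'
#' `log2(normalized + 1)`, the variance-stabilizing surrogate used as input
#' to PCA and sample-correlation analyses.
#' @param norm A `CountMatrix` in `normalized` state.
#' @return A `CountMatrix` in `log` state.
#' @export
log_transform <- function(norm) {
  stopifnot(cm_state(norm) == "normalized")
  count_matrix(log2(as.matrix(norm) + 1), state = "log")
}

#' Per-feature expression Z-scores
#'
#' Centres each feature (row) at zero and scales to unit standard deviation
#' (n - 1 denominator, the R `scale` convention). Features with zero
#' standard deviation are dropped beforehand.
#'
#' @param cm A `CountMatrix` (any state except `zscore`).
#' @return A `CountMatrix` in `zscore` state, possibly with fewer rows.
#' @export
zscore_rows <- function(cm) {
  stopifnot(cm_state(cm) != "zscore")
  m <- as.matrix(cm)
  sds <- apply(m, 1, stats::sd)
  keep <- sds > 0 & !is.na(sds)
  m <- m[keep, , drop = FALSE]
  z <- t(scale(t(m), center = TRUE, scale = TRUE))
  dimnames(z) <- dimnames(m)
  count_matrix(z, state = "zscore", dropped_constant = sum(!keep))
}

#' Principal component analysis of samples
#'
#' PCA on the centred, scaled matrix (samples as observations, features as
#' variables), keeping at most `rank` components. Features with zero
#' standard deviation across samples are removed first.
#'
#' @param cm A `CountMatrix`; `log` state is the conventional input.
#' @param rank Maximum number of components (default 50; further capped at
#'   `min(n_samples - 1, n_features)`).
#' @param scale. Scale features to unit variance (default `TRUE`).
#' @return A list with `scores` (samples x components), `loadings`,
#'   `explained` (fraction of variance per component, non-increasing).
#' @export
run_pca <- function(cm, rank = 50, scale. = TRUE) {
  m <- as.matrix(cm)
  sds <- apply(m, 1, stats::sd)
  m <- m[sds > 0 & !is.na(sds), , drop = FALSE]
  if (nrow(m) == 0) stop("no feature with non-zero s.d.")
  rank <- min(rank, ncol(m) - 1L, nrow(m))
  p <- stats::prcomp(t(m), center = TRUE, scale. = scale., rank. = rank)
  expl <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, loadings = p$rotation,
       explained = expl[seq_len(rank)])
}

#' Sample-by-sample Pearson correlation matrix
#' @param cm A `CountMatrix`; columns are correlated.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sample_cor <- function(cm) {
  stats::cor(as.matrix(cm), method = "pearson")
}
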