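#' Method-of-moments negative-binomial dispersion estimates
#'
#' Per-feature dispersion on normalized counts: for feature i with mean m_i
#' and variance v_i across samples, alpha_i = max(0, (v_i - m_i) / m_i^2),
#' so that Var = m + alpha * m^2. Features with zero mean are excluded
#' (returned as `NA`). There is no shrinkage across features: each feature
#' is treated independently.
#'
#' @param raw A `CountMatrix` in `raw` state.
#' @param sf Size factors (recomputed if missing).
#' @return Named numeric vector of dispersions (NA for mean-zero features).
#' @export
estimate_dispersion <- function(raw, sf = NULL) {
  stopifnot(cm_state(raw) == "raw")
  if (is.null(sf)) sf <- size_factors(raw)
  norm <- sweep(as.matrix(raw), 2, sf, "/")
  m <- rowMeans(norm)
  v <- apply(norm, 1, stats::var)
  alpha <- ifelse(m > 0, pmax(0, (v - m) / m^2), NA_real_)
  stats::setNames(alpha, rownames(raw))
}

#' Covariate-adjusted negative-binomial Wald test
#'
#' Per-feature differential expression between two condition levels,
#' adjusting for sample covariates, in the style of count-based DE tools: a
#' negative-binomial log-linear model with a log size-factor offset is fit
#' per feature by iteratively reweighted least squares, and the condition
#' coefficient is tested with a Wald z statistic (two-sided normal p),
#' followed by Benjamini-Hochberg adjustment over the tested features.
#'
#' Design: `~ covariates + condition`, condition always the last term;
#' continuous covariates are standardized before fitting (this leaves the
#' condition coefficient unchanged). Counts are rounded to the nearest
#' integer, as required by the NB likelihood; dispersions are plugged in
#' from [estimate_dispersion()] with no shrinkage, no independent filtering
#' and no outlier handling. Features whose fit does not converge get
#' `pvalue = NA` and are excluded from the BH denominator.
#'
#' @param raw A `CountMatrix` in `raw` state.
#' @param metadata `data.frame` with one row per sample (matched to columns
#'   of `raw` via `sample_id`), containing `condition` and any covariates.
#' @param covariates Character vector of metadata columns to adjust for,
#'   e.g. `c("age", "gender", "input_volume")`. May be empty.
#' @param condition Name of the two-level condition column.
#' @param reference Reference (baseline) condition level; positive log2
#'   fold changes mean higher in the non-reference level.
#' @param sf,dispersions Optional precomputed size factors / dispersions.
#' @return A `DEResult` `data.frame` with DESeq2-dialect columns: `feature`,
#'   `baseMean`, `log2FoldChange`, `lfcSE`, `pvalue`, `padj`, plus `tested`.
#' @export
nb_wald_test <- function(raw, metadata, covariates = character(0),
                         condition = "condition", reference = NULL,
                         sf = NULL, dispersions = NULL) {
  stopifnot(cm_state(raw) == "raw")
  stopifnot(all(c("sample_id", condition) %in% names(metadata)))
  stopifnot(all(colnames(raw) %in% metadata$sample_id))
  meta <- metadata[match(colnames(raw), metadata$sample_id), , drop = FALSE]

  cond <- as.character(meta[[condition]])
  levs <- unique(cond)
  if (length(levs) != 2) {
    stop("condition must have exactly two levels; got ",
         paste(levs, collapse = ", "))
  }
  if (is.null(reference)) reference <- sort(levs)[1]
  stopifnot(reference %in% levs)
  cond <- factor(cond, levels = c(reference, setdiff(levs, reference)))

  if (is.null(sf)) sf <- size_factors(raw)
  if (is.null(dispersions)) dispersions <- estimate_dispersion(raw, sf)
  counts <- round(as.matrix(raw))
  offset <- log(sf)

  # design matrix: intercept + standardized covariates + condition (last)
  df <- data.frame(row.names = meta$sample_id)
  for (cv in covariates) {
    v <- meta[[cv]]
    if (is.numeric(v)) {
      s <- stats::sd(v)
      df[[cv]] <- if (s > 0) (v - mean(v)) / s else v * 0
    } else {
      df[[cv]] <- factor(v)
    }
  }
  df$.condition <- cond
  X <- stats::model.matrix(~ ., data = df)
  if (qr(X)$rank < ncol(X)) stop("collinear design matrix")
  cond_col <- ncol(X)  # condition dummy is the last column

  norm <- sweep(counts, 2, sf, "/")
  n_feat <- nrow(counts)
  log2fc <- se <- pval <- rep(NA_real_, n_feat)
  tested <- rep(FALSE, n_feat)
  for (i in seq_len(n_feat)) {
    y <- counts[i, ]
    a <- dispersions[i]
    if (is.na(a) || all(y == 0)) next
    fam <- if (a < 1e-8) stats::poisson() else
      MASS::negative.binomial(theta = 1 / a)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y, family = fam, offset = offset)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$boundary) next
    p1 <- seq_len(fit$rank)
    if (fit$rank < ncol(X)) next
    covmat <- tryCatch(chol2inv(fit$qr$qr[p1, p1, drop = FALSE]),
                       error = function(e) NULL)
    if (is.null(covmat)) next
    piv <- fit$qr$pivot[p1]
    pos <- which(piv == cond_col)
    beta <- fit$coefficients[cond_col]
    s <- sqrt(covmat[pos, pos])
    if (!is.finite(beta) || !is.finite(s) || s <= 0) next
    log2fc[i] <- beta / log(2)
    se[i] <- s / log(2)
    pval[i] <- 2 * stats::pnorm(-abs(beta / s))
    tested[i] <- TRUE
  }
  out <- data.frame(
    feature = rownames(counts),
    baseMean = rowMeans(norm),
    log2FoldChange = log2fc,
    lfcSE = se,
    pvalue = pval,
    padj = NA_real_,
    tested = tested,
    stringsAsFactors = FALSE
  )
  out$padj[tested] <- bh_adjust(pval[tested])
  class(out) <- c("DEResult", "data.frame")
  attr(out, "design") <- paste("~", paste(c(covariates, condition),
                                          collapse = " + "))
  attr(out, "reference") <- reference
  # provenance: which samples the result was computed on (leakage guard)
  attr(out, "samples") <- colnames(raw)
  out
}

#' Volcano-plot table
#'
#' Per-feature effect size against significance:
#' `-log10(padj)` versus log2 fold change, with each feature classed as
#' `up` (padj < `alpha`, log2fc > 0), `down` (padj < `alpha`, log2fc < 0)
#' or `ns` otherwise.
#' @param de A `DEResult`.
#' @param alpha Adjusted-p significance cutoff (default 0.01).
#' @return `data.frame` with `feature`, `log2FoldChange`, `neg_log10_padj`,
#'   `class`.
#' @export
volcano_table <- function(de, alpha = 0.01) {
  cls <- rep("ns", nrow(de))
  sig <- !is.na(de$padj) & de$padj < alpha
  cls[sig & de$log2FoldChange > 0] <- "up"
  cls[sig & de$log2FoldChange < 0] <- "down"
  data.frame(feature = de$feature,
             log2FoldChange = de$log2FoldChange,
             neg_log10_padj = -log10(de$padj),
             class = cls,
             stringsAsFactors = FALSE)
}

#' Shared and unique repeat signatures across diseases
#'
#' For each disease's DE result, the up-regulated repeat-subfamily set is
#' `{rmsk features: padj < alpha, log2fc > 0}` (down analogous). Exclusive
#' intersection cardinalities are computed over the full disease power set,
#' the quantities displayed by an UpSet plot.
#'
#' @param de_list Named list of `DEResult`s, one per disease.
#' @param alpha Adjusted-p cutoff (default 0.01).
#' @return `data.frame` with columns `direction` (up/down), `combination`
#'   (disease names joined by `&`), `count`, plus attribute `sets` holding
#'   the underlying feature sets.
#' @export
signature_overlap <- function(de_list, alpha = 0.01) {
  stopifnot(length(de_list) >= 1, !is.null(names(de_list)))
  pick <- function(de, up) {
    sig <- !is.na(de$padj) & de$padj < alpha &
      startsWith(de$feature, "rmsk:") &
      (if (up) de$log2FoldChange > 0 else de$log2FoldChange < 0)
    de$feature[sig]
  }
  sets <- list(up = lapply(de_list, pick, up = TRUE),
               down = lapply(de_list, pick, up = FALSE))
  diseases <- names(de_list)
  rows <- list()
  for (dir in c("up", "down")) {
    s <- sets[[dir]]
    universe <- unique(unlist(s))
    membership <- matrix(FALSE, nrow = length(universe),
                         ncol = length(diseases),
                         dimnames = list(universe, diseases))
    for (d in diseases) membership[, d] <- universe %in% s[[d]]
    for (k in seq_along(diseases)) {
      for (combo in utils::combn(diseases, k, simplify = FALSE)) {
        inside <- rowSums(membership[, combo, drop = FALSE]) == length(combo)
        outside <- rowSums(membership[, setdiff(diseases, combo),
                                      drop = FALSE]) == 0
        rows[[length(rows) + 1]] <- data.frame(
          direction = dir,
          combination = paste(combo, collapse = "&"),
          count = sum(inside & outside),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "sets") <- sets
  out
}

#' Write a DE table in the DESeq2 column dialect
#' @param de A `DEResult`.
#' @param path Output TSV path.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(
    de[, c("feature", "baseMean", "log2FoldChange", "lfcSE", "pvalue", "padj")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
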