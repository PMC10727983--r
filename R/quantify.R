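#' Read a per-sample quantification table
#'
#' Reads the `quant.sf` TSV dialect produced by alignment-free quantifiers:
#' columns `Name`, `Length`, `EffectiveLength`, `TPM`, `NumReads`.
#'
#' @param path Path to the TSV.
#' @param sample_id Sample identifier; defaults to the file's base name
#'   without extension.
#' @param total_input_reads Optional total number of sequenced reads for the
#'   sample (used for mapping-rate computation).
#' @return A `QuantTable`: `data.frame` with columns `unit_id`, `length`,
#'   `effective_length`, `tpm`, `num_reads`; attributes `sample_id` and
#'   `total_input_reads`.
#' @export
read_quant <- function(path, sample_id = NULL, total_input_reads = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  required <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0) {
    stop("quant table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(tab$Name)) {
    stop("duplicated unit name in quant table: ",
         tab$Name[duplicated(tab$Name)][1])
  }
  if (any(tab$NumReads < 0)) stop("negative NumReads in quant table")
  out <- data.frame(unit_id = as.character(tab$Name),
                    length = as.numeric(tab$Length),
                    effective_length = as.numeric(tab$EffectiveLength),
                    tpm = as.numeric(tab$TPM),
                    num_reads = as.numeric(tab$NumReads),
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- if (is.null(sample_id)) {
    sub("\\.[^.]*$", "", basename(path))
  } else sample_id
  attr(out, "total_input_reads") <- total_input_reads
  class(out) <- c("QuantTable", "data.frame")
  out
}

#' Construct a QuantTable in memory
#'
#' Convenience constructor used by the toy quantifier and tests.
#' @param unit_id,num_reads Unit ids and estimated read counts.
#' @param length Unit lengths in nt (default `NA`).
#' @param sample_id Sample identifier.
#' @param total_input_reads Optional total sequenced reads.
#' @return A `QuantTable` (see [read_quant()]).
#' @export
quant_table <- function(unit_id, num_reads, length = NA_real_,
                        sample_id, total_input_reads = NULL) {
  stopifnot(!anyDuplicated(unit_id), all(num_reads >= 0))
  out <- data.frame(unit_id = as.character(unit_id), length = length,
                    effective_length = length, tpm = NA_real_,
                    num_reads = as.numeric(num_reads),
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  attr(out, "total_input_reads") <- total_input_reads
  class(out) <- c("QuantTable", "data.frame")
  out
}

#' Write a QuantTable in the quant.sf dialect
#' @param qt A `QuantTable`.
#' @param path Output TSV path.
#' @export
write_quant <- function(qt, path) {
  out <- data.frame(Name = qt$unit_id, Length = qt$length,
                    EffectiveLength = qt$effective_length,
                    TPM = ifelse(is.na(qt$tpm), 0, qt$tpm),
                    NumReads = qt$num_reads)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Aggregate unit-level quantifications to feature-level counts
#'
#' Sums estimated reads over all units mapping to the same catalog feature,
#' per sample — transcripts to their gene, repeat instances to their
#' subfamily. Fractional counts from probabilistic read assignment are
#' preserved. Units absent from the catalog are dropped with a warning and
#' listed in the result's `unresolved` attribute.
#'
#' @param tables List of `QuantTable`s (one per sample).
#' @param catalog A `FeatureCatalog`.
#' @return A `CountMatrix` in `raw` state: features x samples. Every catalog
#'   feature is present (zero row if never observed). Attribute
#'   `assigned_reads` holds per-sample totals of resolvable reads;
#'   `total_input_reads` the per-sample sequencing totals where known.
#' @export
aggregate_counts <- function(tables, catalog) {
  stopifnot(inherits(catalog, "FeatureCatalog"))
  sample_ids <- vapply(tables, function(t) attr(t, "sample_id"), "")
  if (anyDuplicated(sample_ids)) {
    stop("sample_id collision: ", sample_ids[duplicated(sample_ids)][1])
  }
  fids <- catalog$features$feature_id
  map <- stats::setNames(catalog$unit_map$feature_id, catalog$unit_map$unit_id)
  m <- matrix(0, nrow = length(fids), ncol = length(tables),
              dimnames = list(fids, sample_ids))
  unresolved <- character(0)
  totals <- vapply(tables, function(t) {
    v <- attr(t, "total_input_reads")
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, 0)
  for (j in seq_along(tables)) {
    t <- tables[[j]]
    f <- unname(map[t$unit_id])
    bad <- is.na(f)
    if (any(bad)) unresolved <- union(unresolved, t$unit_id[bad])
    agg <- rowsum(t$num_reads[!bad], f[!bad])
    m[rownames(agg), j] <- agg[, 1]
  }
  if (length(unresolved) > 0) {
    warning(length(unresolved), " unit(s) absent from catalog dropped during aggregation")
  }
  count_matrix(m, state = "raw", unresolved = unresolved,
               assigned_reads = colSums(m),
               total_input_reads = stats::setNames(totals, sample_ids))
}

#' Per-sample mapping rate
#'
#' Fraction of sequenced reads assigned to catalog features. Used to compare
#' repeat-naive against repeat-aware references: where repeat-derived reads
#' exist, the repeat-aware reference recovers them and its rate is higher;
#' the paired two-sided Wilcoxon signed-rank test ([wilcoxon_rank_sum()])
#' quantifies the gain across samples.
#'
#' @param assigned Named numeric vector of per-sample assigned reads (e.g.
#'   `attr(cm, "assigned_reads")`).
#' @param total_input_reads Named numeric vector of per-sample totals.
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
mapping_rate <- function(assigned, total_input_reads) {
  stopifnot(all(total_input_reads > 0))
  if (any(assigned > total_input_reads + 1e-9)) {
    stop("assigned reads exceed total input reads")
  }
  pmin(assigned / total_input_reads, 1)
}
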