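#' Read aligned long-read fragments
#'
#' Reads the fragment TSV dialect (`read_id`, `chrom`, `start`, `end`,
#' `template_length`; 0-based half-open intervals). `template_length` is
#' the observed cell-free RNA length of the fragment.
#'
#' @param path TSV path.
#' @return `data.frame` of fragments; rows with non-positive template
#'   length are rejected with a warning.
#' @export
read_fragments <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE)
  required <- c("read_id", "chrom", "start", "end", "template_length")
  miss <- setdiff(required, names(tab))
  if (length(miss) > 0) stop("fragment table missing column(s): ",
                             paste(miss, collapse = ", "))
  bad <- tab$template_length <= 0
  if (any(bad)) {
    warning(sum(bad), " fragment(s) with non-positive template length rejected")
    tab <- tab[!bad, , drop = FALSE]
  }
  tab
}

#' Choose the annotation whose length is closest to the fragment's
#'
#' Among candidate overlapping annotations, picks the one minimizing
#' `|annotation_length - template_length|`; ties are broken by the smaller
#' annotation length, then lexicographically by unit id. With no
#' candidates the fragment is unannotated (`NA`).
#'
#' @param template_length Observed fragment length (nt).
#' @param candidates `data.frame` with columns `unit_id`,
#'   `annotation_length`, `group` (possibly 0 rows).
#' @return One-row `data.frame` (`unit_id`, `annotation_length`, `group`),
#'   or an all-`NA` row when there are no candidates.
#' @export
resolve_annotation <- function(template_length, candidates) {
  if (is.null(candidates) || nrow(candidates) == 0) {
    return(data.frame(unit_id = NA_character_,
                      annotation_length = NA_real_,
                      group = NA_character_, stringsAsFactors = FALSE))
  }
  d <- abs(candidates$annotation_length - template_length)
  ord <- order(d, candidates$annotation_length, candidates$unit_id)
  candidates[ord[1], c("unit_id", "annotation_length", "group"),
             drop = FALSE]
}

#' Annotate fragments by overlap and closest length
#'
#' Candidate annotations are all catalog units whose genomic interval
#' intersects the fragment's aligned interval by at least 1 bp (same
#' chromosome); each fragment is then resolved to the candidate with the
#' closest length via [resolve_annotation()].
#'
#' @param frags Fragment `data.frame` from [read_fragments()].
#' @param units Catalog unit table (`catalog$units`): `unit_id`, `chrom`,
#'   `start`, `end`, `group`.
#' @return `frags` with added columns `unit_id`, `annotation_length`,
#'   `group` (`NA` for unannotated fragments) and `n_candidates`.
#' @export
annotate_fragments <- function(frags, units) {
  units$annotation_length <- units$end - units$start
  frags$unit_id <- NA_character_
  frags$annotation_length <- NA_real_
  frags$group <- NA_character_
  frags$n_candidates <- 0L
  for (chr in unique(frags$chrom)) {
    fi <- which(frags$chrom == chr)
    ui <- which(units$chrom == chr)
    if (length(ui) == 0) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = frags$start[fi] + 1L, end = frags$end[fi]),
      IRanges::IRanges(start = units$start[ui] + 1L, end = units$end[ui]),
      minoverlap = 1L)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    for (k in unique(qh)) {
      cand <- units[ui[sh[qh == k]],
                    c("unit_id", "annotation_length", "group"),
                    drop = FALSE]
      res <- resolve_annotation(frags$template_length[fi[k]], cand)
      frags$unit_id[fi[k]] <- res$unit_id
      frags$annotation_length[fi[k]] <- res$annotation_length
      frags$group[fi[k]] <- res$group
      frags$n_candidates[fi[k]] <- nrow(cand)
    }
  }
  frags
}

#' Per-group fragment-length summaries
#'
#' Median (midpoint convention), maximum and count of observed fragment
#' lengths per annotation group, with the full length vectors attached for
#' distribution plotting.
#'
#' @param frags Annotated fragments ([annotate_fragments()]); unannotated
#'   fragments are summarised under group `"unannotated"`.
#' @return `data.frame` with `group`, `n`, `median_length`, `max_length`;
#'   attribute `lengths` holds the per-group length vectors.
#' @export
length_summary <- function(frags) {
  grp <- ifelse(is.na(frags$group), "unannotated", frags$group)
  groups <- sort(unique(grp))
  lens <- lapply(groups, function(g) sort(frags$template_length[grp == g]))
  names(lens) <- groups
  out <- data.frame(
    group = groups,
    n = vapply(lens, length, 0L),
    median_length = vapply(lens, stats::median, 0),
    max_length = vapply(lens, max, 0),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "lengths") <- lens
  out
}

#' Observed-to-expected length ratios
#'
#' Per-fragment ratio of observed template length to the length of the
#' resolved annotation, flagged as `full_length` (ratio >= `full_min`),
#' `half_length` (ratio within `half_window`) or `other`. Near-unity ratios
#' indicate full-length transcripts of the annotated element; ratios around
#' 0.5 indicate a half-length RNA species.
#'
#' @param frags Annotated fragments (unannotated rows are dropped).
#' @param full_min Full-length ratio threshold (default 0.9).
#' @param half_window Half-length ratio window (default `c(0.4, 0.6)`).
#' @return `frags` subset with added `ratio` and `length_class` columns.
#' @export
observed_vs_expected <- function(frags, full_min = 0.9,
                                 half_window = c(0.4, 0.6)) {
  frags <- frags[!is.na(frags$unit_id), , drop = FALSE]
  frags$ratio <- frags$template_length / frags$annotation_length
  cls <- rep("other", nrow(frags))
  cls[frags$ratio >= full_min] <- "full_length"
  cls[frags$ratio >= half_window[1] & frags$ratio <= half_window[2]] <-
    "half_length"
  frags$length_class <- cls
  frags
}

#' Modes of a length distribution
#'
#' Local maxima of a Gaussian kernel density estimate, returned in
#' decreasing order of density height. Used to detect bimodality, e.g. the
#' full-length (~300 nt) and half-length (~150 nt) components of SINE
#' fragment lengths.
#'
#' @param lengths Numeric vector of lengths.
#' @param bw Kernel bandwidth (default `"SJ"` fallback to `"nrd0"`).
#' @param min_height Minimum density height relative to the tallest mode
#'   (default 0.1) below which a local maximum is ignored.
#' @return Numeric vector of mode locations (nt).
#' @export
find_length_modes <- function(lengths, bw = "nrd0", min_height = 0.1) {
  stopifnot(length(lengths) >= 10)
  d <- stats::density(lengths, bw = bw)
  y <- d$y
  loc <- which(y > c(y[-1], -Inf) & y > c(-Inf, y[-length(y)]))
  loc <- loc[y[loc] >= min_height * max(y)]
  d$x[loc[order(-y[loc])]]
}
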