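#' Parse a RepeatMasker-style repeat table
#'
#' Reads the UCSC `rmsk` TSV dialect (columns `genoName`, `genoStart`,
#' `genoEnd`, `strand`, `repName`, `repClass`, `repFamily`; an optional `bin`
#' column and header line are tolerated) into a table of repeat instances,
#' one row per genomic insertion. Coordinates are kept 0-based half-open as
#' stored in the table. The rmsk complement strand notation `"C"` is
#' normalised to `"-"`. A `"?"` suffix on `repClass` (uncertain
#' classification, e.g. `"SINE?"`) is stripped for the `superfamily`
#' grouping; the raw value is retained in `superfamily_raw`.
#'
#' @param path Path to the rmsk-dialect TSV (or a connection).
#' @return A `data.frame` with one row per instance and columns
#'   `instance_id`, `chrom`, `start`, `end`, `strand`, `subfamily`,
#'   `family`, `superfamily`, `superfamily_raw`. The number of rejected
#'   rows (with `genoStart >= genoEnd`) is recorded in attribute
#'   `"n_rejected"`.
#' @examples
#' f <- tempfile()
#' writeLines(c("genoName\tgenoStart\tgenoEnd\tstrand\trepName\trepClass\trepFamily",
#'              "chr1\t100\t406\t+\tAluY\tSINE\tAlu"), f)
#' parse_rmsk(f)
#' @export
parse_rmsk <- function(path) {
  required <- c("genoName", "genoStart", "genoEnd", "strand",
                "repName", "repClass", "repFamily")
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", fill = TRUE,
                           stringsAsFactors = FALSE)
  header_line <- 0L
  if (nrow(raw) > 0 && all(required %in% as.character(unlist(raw[1, ])))) {
    names(raw) <- as.character(unlist(raw[1, ]))
    raw <- raw[-1, , drop = FALSE]
    header_line <- 1L
  } else {
    # headerless table: positional, with or without the UCSC bin column
    nc <- ncol(raw)
    if (nc == 7L) {
      names(raw) <- required
    } else if (nc == 8L) {
      names(raw) <- c("bin", required)
    } else {
      stop("rmsk table must have 7 (or 8, with bin) columns or a named header; got ",
           nc, " columns")
    }
  }
  raw <- raw[, required, drop = FALSE]

  start <- suppressWarnings(as.numeric(raw$genoStart))
  end <- suppressWarnings(as.numeric(raw$genoEnd))
  bad <- which(is.na(start) | is.na(end) | raw$genoName == "" |
                 raw$repName == "" | !(raw$strand %in% c("+", "-", "C")))
  if (length(bad) > 0) {
    stop("malformed rmsk row at line ", bad[1] + header_line,
         ": ", paste(raw[bad[1], ], collapse = "\t"))
  }

  inverted <- start >= end
  n_rejected <- sum(inverted)
  if (n_rejected > 0) {
    warning(n_rejected, " rmsk row(s) with genoStart >= genoEnd rejected (lines ",
            paste(which(inverted) + header_line, collapse = ", "), ")")
  }
  keep <- !inverted
  strand <- ifelse(raw$strand[keep] == "C", "-", raw$strand[keep])
  out <- data.frame(
    chrom = raw$genoName[keep],
    start = start[keep],
    end = end[keep],
    strand = strand,
    subfamily = raw$repName[keep],
    family = raw$repFamily[keep],
    superfamily = sub("\\?$", "", raw$repClass[keep]),
    superfamily_raw = raw$repClass[keep],
    stringsAsFactors = FALSE
  )
  out$instance_id <- sprintf("%s:%s:%d-%d(%s)", out$subfamily, out$chrom,
                             as.integer(out$start), as.integer(out$end),
                             out$strand)
  if (anyDuplicated(out$instance_id)) {
    # identical coordinates can occur in degenerate toy tables; disambiguate
    dup <- duplicated(out$instance_id)
    out$instance_id[dup] <- paste0(out$instance_id[dup], "#",
                                   seq_len(sum(dup)))
  }
  out <- out[, c("instance_id", "chrom", "start", "end", "strand",
                 "subfamily", "family", "superfamily", "superfamily_raw")]
  rownames(out) <- NULL
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Parse gene and transcript records from a GTF
#'
#' Reads a GENCODE-dialect GTF and returns one record per gene with its
#' transcripts attached. Only `gene` and `transcript` feature lines are
#' used; parsing is order-independent, so a transcript line may precede its
#' gene line. GTF coordinates (1-based inclusive) are converted to 0-based
#' half-open.
#'
#' @param path Path to the GTF file.
#' @return A `data.frame` with columns `gene_id`, `gene_name`, `biotype`,
#'   `chrom`, `start`, `end`, `strand` and a list-column `transcript_ids`.
#' @export
parse_gtf_genes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9)) {
    stop("malformed GTF line ", which(nf < 9)[1], ": fewer than 9 fields")
  }
  ftype <- vapply(fields, `[[`, "", 3L)
  keep <- ftype %in% c("gene", "transcript")
  fields <- fields[keep]
  ftype <- ftype[keep]

  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
    if (length(m) == 0) return(NA_character_)
    sub(paste0(key, ' "([^"]*)"'), "\\1", m)
  }

  genes <- list()
  tx_gene <- character(0)   # names = transcript_id, values = gene_id
  for (f in seq_along(fields)) {
    x <- fields[[f]]
    attrs <- x[[9L]]
    gid <- attr_get(attrs, "gene_id")
    if (is.na(gid)) stop("GTF record without gene_id attribute")
    if (ftype[f] == "gene") {
      bt <- attr_get(attrs, "gene_type")
      if (is.na(bt)) {
        warning("gene ", gid, " has no gene_type attribute; biotype set to 'unknown'")
        bt <- "unknown"
      }
      gname <- attr_get(attrs, "gene_name")
      genes[[gid]] <- list(
        gene_id = gid,
        gene_name = if (is.na(gname)) gid else gname,
        biotype = bt,
        chrom = x[[1L]],
        start = as.numeric(x[[4L]]) - 1,  # to 0-based half-open
        end = as.numeric(x[[5L]]),
        strand = x[[7L]]
      )
    } else {
      tid <- attr_get(attrs, "transcript_id")
      if (is.na(tid)) stop("transcript record without transcript_id attribute")
      tx_gene[tid] <- gid
    }
  }
  unknown <- setdiff(unique(unname(tx_gene)), names(genes))
  if (length(unknown) > 0) {
    stop("transcript(s) reference unknown gene_id: ",
         paste(unknown, collapse = ", "))
  }
  out <- do.call(rbind, lapply(genes, function(g) {
    data.frame(gene_id = g$gene_id, gene_name = g$gene_name,
               biotype = g$biotype, chrom = g$chrom, start = g$start,
               end = g$end, strand = g$strand, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$transcript_ids <- lapply(out$gene_id, function(g) {
    names(tx_gene)[tx_gene == g]
  })
  out
}

#' Build a repeat-aware feature catalog
#'
#' Unifies gene features and repeat-subfamily features into a single feature
#' namespace and records the many-to-one map from quantification units
#' (transcripts and repeat instances) to features. Repeat instances are
#' aggregated to one feature per distinct subfamily name; repeat feature ids
#' are namespaced as `rmsk:<subfamily>` so they can never collide with gene
#' ids.
#'
#' @param genes `data.frame` from [parse_gtf_genes()] (required unless
#'   `mode = "repeat_alone"`).
#' @param instances `data.frame` from [parse_rmsk()] (required unless
#'   `mode = "repeat_naive"`).
#' @param mode One of `"repeat_aware"` (genes + subfamilies),
#'   `"repeat_naive"` (genes only), `"repeat_alone"` (subfamilies only).
#' @return A `FeatureCatalog`: list with `features` (feature_id,
#'   feature_class, group, display_name), `unit_map` (unit_id -> feature_id),
#'   `units` (per-unit coordinates and lengths, for sequence extraction and
#'   overlap queries) and `mode`.
#' @export
build_catalog <- function(genes = NULL, instances = NULL,
                          mode = c("repeat_aware", "repeat_naive", "repeat_alone")) {
  mode <- match.arg(mode)
  need_genes <- mode %in% c("repeat_aware", "repeat_naive")
  need_reps <- mode %in% c("repeat_aware", "repeat_alone")
  if (need_genes && (is.null(genes) || nrow(genes) == 0)) {
    stop("mode '", mode, "' requires gene records")
  }
  if (need_reps && (is.null(instances) || nrow(instances) == 0)) {
    stop("mode '", mode, "' requires repeat instances")
  }

  feats <- list()
  maps <- list()
  units <- list()
  if (need_genes) {
    if (anyDuplicated(genes$gene_id)) {
      stop("duplicate gene_id: ",
           genes$gene_id[duplicated(genes$gene_id)][1])
    }
    feats$genes <- data.frame(
      feature_id = genes$gene_id,
      feature_class = "gene",
      group = genes$biotype,
      display_name = genes$gene_name,
      stringsAsFactors = FALSE
    )
    ntx <- lengths(genes$transcript_ids)
    maps$genes <- data.frame(
      unit_id = unlist(genes$transcript_ids, use.names = FALSE),
      feature_id = rep(genes$gene_id, ntx),
      stringsAsFactors = FALSE
    )
    if (anyDuplicated(maps$genes$unit_id)) {
      stop("transcript mapped to more than one gene: ",
           maps$genes$unit_id[duplicated(maps$genes$unit_id)][1])
    }
    # toy transcripts span their gene locus (no splicing model)
    units$genes <- data.frame(
      unit_id = maps$genes$unit_id,
      chrom = rep(genes$chrom, ntx),
      start = rep(genes$start, ntx),
      end = rep(genes$end, ntx),
      strand = rep(genes$strand, ntx),
      group = rep(genes$biotype, ntx),
      stringsAsFactors = FALSE
    )
  }
  if (need_reps) {
    subfam <- unique(instances[, c("subfamily", "superfamily")])
    # a subfamily keeps the superfamily of its first occurrence
    subfam <- subfam[!duplicated(subfam$subfamily), , drop = FALSE]
    feats$repeats <- data.frame(
      feature_id = paste0("rmsk:", subfam$subfamily),
      feature_class = "repeat_subfamily",
      group = subfam$superfamily,
      display_name = subfam$subfamily,
      stringsAsFactors = FALSE
    )
    maps$repeats <- data.frame(
      unit_id = instances$instance_id,
      feature_id = paste0("rmsk:", instances$subfamily),
      stringsAsFactors = FALSE
    )
    units$repeats <- data.frame(
      unit_id = instances$instance_id,
      chrom = instances$chrom,
      start = instances$start,
      end = instances$end,
      strand = instances$strand,
      group = instances$superfamily,
      stringsAsFactors = FALSE
    )
  }
  features <- do.call(rbind, unname(feats))
  unit_map <- do.call(rbind, unname(maps))
  unit_tab <- do.call(rbind, unname(units))
  rownames(features) <- rownames(unit_map) <- rownames(unit_tab) <- NULL
  stopifnot(!anyDuplicated(features$feature_id),
            !anyDuplicated(unit_map$unit_id))
  structure(list(features = features, unit_map = unit_map,
                 units = unit_tab, mode = mode),
            class = "FeatureCatalog")
}

#' @export
print.FeatureCatalog <- function(x, ...) {
  cat("FeatureCatalog (mode: ", x$mode, ")\n", sep = "")
  tab <- table(x$features$feature_class)
  for (cl in names(tab)) cat("  ", cl, ": ", tab[[cl]], " features\n", sep = "")
  cat("  units mapped: ", nrow(x$unit_map), "\n", sep = "")
  invisible(x)
}

#' Summarise a feature catalog
#'
#' Feature counts per class and per group, suitable for serialising to JSON.
#' @param catalog A `FeatureCatalog`.
#' @return A list with `mode`, `n_features`, `n_units`, and per-class /
#'   per-group count tables.
#' @export
catalog_summary <- function(catalog) {
  stopifnot(inherits(catalog, "FeatureCatalog"))
  list(
    mode = catalog$mode,
    n_features = nrow(catalog$features),
    n_units = nrow(catalog$unit_map),
    by_class = as.list(table(catalog$features$feature_class)),
    by_group = as.list(table(catalog$features$group))
  )
}

#' Write / read the unit-to-feature map
#'
#' The two-column TSV (`unit_id`, `feature_id`) is the analogue of the
#' transcript-to-gene ("t2g") table used by alignment-free quantifiers.
#' @param catalog A `FeatureCatalog`.
#' @param path Output TSV path.
#' @export
write_unit_map <- function(catalog, path) {
  stopifnot(inherits(catalog, "FeatureCatalog"))
  utils::write.table(catalog$unit_map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_unit_map
#' @return `read_unit_map` returns the `unit_id`/`feature_id` `data.frame`.
#' @export
read_unit_map <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = "character", quote = "",
                    stringsAsFactors = FALSE)
}

#' Extract reference sequences for catalog units
#'
#' Pulls the genomic sequence for each unit interval; minus-strand units are
#' reverse-complemented. Record length always equals `end - start`.
#'
#' @param genome A [Biostrings::DNAStringSet] or path to a genome FASTA.
#' @param units `data.frame` with columns `unit_id`, `chrom`, `start`,
#'   `end`, `strand` (0-based half-open), e.g. `catalog$units`.
#' @return A [Biostrings::DNAStringSet] named by `unit_id`.
#' @export
extract_sequences <- function(genome, units) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  missing_chr <- setdiff(unique(units$chrom), names(genome))
  if (length(missing_chr) > 0) {
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  }
  widths <- Biostrings::width(genome)[match(units$chrom, names(genome))]
  oob <- units$start < 0 | units$end > widths | units$start >= units$end
  if (any(oob)) {
    stop("unit interval(s) out of bounds: ",
         paste(units$unit_id[oob][seq_len(min(5, sum(oob)))], collapse = ", "))
  }
  seqs <- Biostrings::DNAStringSet(lapply(seq_len(nrow(units)), function(i) {
    Biostrings::subseq(genome[[units$chrom[i]]],
                       start = units$start[i] + 1L,
                       end = units$end[i])
  }))
  minus <- units$strand == "-"
  if (any(minus)) {
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  }
  names(seqs) <- units$unit_id
  seqs
}
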