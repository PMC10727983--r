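# Small in-code fixtures shared across test files.

# gene table in the shape returned by parse_gtf_genes()
make_genes <- function(ids = c("G1", "G2"),
                       biotypes = c("protein_coding", "lncRNA"),
                       tx_per_gene = c(2, 1)) {
  n <- length(ids)
  data.frame(
    gene_id = ids,
    gene_name = ids,
    biotype = rep_len(biotypes, n),
    chrom = "chr1",
    start = seq(0, by = 2000, length.out = n),
    end = seq(1000, by = 2000, length.out = n),
    strand = "+",
    stringsAsFactors = FALSE
  ) -> g
  g$transcript_ids <- lapply(seq_len(n), function(i) {
    paste0(ids[i], ".t", seq_len(rep_len(tx_per_gene, n)[i]))
  })
  g
}

# instance table in the shape returned by parse_rmsk()
make_instances <- function(subfamilies = c("AluY", "AluY", "AluY", "L1HS", "L1HS"),
                           superfamilies = NULL,
                           chrom = "chr1", start0 = 10000, width = 300) {
  n <- length(subfamilies)
  if (is.null(superfamilies)) {
    superfamilies <- ifelse(startsWith(subfamilies, "Alu"), "SINE", "LINE")
  }
  starts <- start0 + (seq_len(n) - 1) * (width + 100)
  out <- data.frame(
    chrom = chrom, start = starts, end = starts + width,
    strand = rep(c("+", "-"), length.out = n),
    subfamily = subfamilies,
    family = subfamilies,
    superfamily = rep_len(superfamilies, n),
    superfamily_raw = rep_len(superfamilies, n),
    stringsAsFactors = FALSE
  )
  out$instance_id <- sprintf("%s:%s:%d-%d(%s)", out$subfamily, out$chrom,
                             out$start, out$end, out$strand)
  out[, c("instance_id", "chrom", "start", "end", "strand", "subfamily",
          "family", "superfamily", "superfamily_raw")]
}

make_catalog <- function(mode = "repeat_aware", genes = make_genes(),
                         instances = make_instances()) {
  build_catalog(genes, instances, mode = mode)
}

# tiny raw CountMatrix
make_counts <- function(m = NULL, n_feat = 20, n_samp = 6, seed = 42) {
  if (is.null(m)) {
    set.seed(seed)
    m <- matrix(rnbinom(n_feat * n_samp, mu = 50, size = 5),
                n_feat, n_samp,
                dimnames = list(paste0("F", seq_len(n_feat)),
                                paste0("S", seq_len(n_samp))))
  }
  count_matrix(m, state = "raw")
}

# parse a toy-genome truth object's annotations via the real parsers
parse_rmsk_df <- function(truth) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(truth$rmsk, f, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  parse_rmsk(f)
}

parse_gtf_df <- function(truth) {
  f <- tempfile(fileext = ".gtf")
  writeLines(truth$gtf_lines, f)
  parse_gtf_genes(f)
}

# exact two-sided enumeration of the rank-sum null (no ties assumed)
enumerate_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_u <- apply(combn(n1 + n2, n1), 2, function(idx) {
    sum(seq_len(n1 + n2)[idx]) - n1 * (n1 + 1) / 2
  })
  lo <- mean(all_u <= u_obs)
  hi <- mean(all_u >= u_obs)
  min(1, 2 * min(lo, hi))
}

# pair-counting AUC oracle
pair_auc <- function(prob, labels) {
  labels <- as.logical(labels)
  ca <- prob[labels]; co <- prob[!labels]
  tot <- 0
  for (a in ca) tot <- tot + sum(a > co) + 0.5 * sum(a == co)
  tot / (length(ca) * length(co))
}
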