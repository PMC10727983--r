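#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with documented
#' defaults: a 60-sample cohort (30 healthy, 30 disease), a toy genome with
#' Alu-like 300-nt SINE subfamilies, an LTR-like subfamily and a simple
#' repeat, NB-distributed counts with a planted two-log2-unit enrichment of
#' Alu-like subfamilies in disease, log-normal library sizes, additive
#' covariate effects, and the bimodal SINE fragment-length mixture
#' (0.5 N(300, 20^2) + 0.5 N(150, 15^2)).
#'
#' @param seed Integer seed (mandatory); per-stage sub-seeds are derived
#'   deterministically from it.
#' @param n_healthy,n_case Cohort arm sizes.
#' @param n_genes Number of toy genes.
#' @param subfamilies Named list describing repeat subfamilies: each entry
#'   `list(superfamily =, family =, length =, n_instances =)`.
#' @param mutation_rate Per-base substitution rate applied to each planted
#'   instance relative to its subfamily consensus.
#' @param planted_up Named numeric vector of planted condition log2 fold
#'   changes, keyed by feature id (e.g. `c("rmsk:AluY" = 2)`).
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2);
#'   0 gives the Poisson limit.
#' @param libsize_sd Standard deviation of the log-normal library-size
#'   model (log scale).
#' @param covariate_effects Named numeric vector of log2-scale effects per
#'   standardized covariate unit, for `age`, `gender`, `input_volume`.
#' @param reads_per_sample Expected sequenced reads per sample (read-level
#'   simulation).
#' @param read_length Read length in nt (read-level simulation).
#' @param frac_background Fraction of reads drawn from intergenic
#'   background (unassignable to any catalog unit).
#' @param fragment_spec Named list of per-group length mixtures:
#'   `list(weights =, means =, sds =)`.
#' @param n_fragments Fragments to simulate.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_healthy = 30, n_case = 30,
                       n_genes = 30,
                       subfamilies = list(
                         AluY = list(superfamily = "SINE", family = "Alu",
                                     length = 300, n_instances = 10),
                         AluSx = list(superfamily = "SINE", family = "Alu",
                                      length = 300, n_instances = 10),
                         L1HS = list(superfamily = "LINE", family = "L1",
                                     length = 1000, n_instances = 6),
                         THE1B = list(superfamily = "LTR", family = "ERVL-MaLR",
                                      length = 350, n_instances = 6),
                         `(TA)n` = list(superfamily = "Simple_repeat",
                                        family = "Simple_repeat",
                                        length = 120, n_instances = 6)),
                       mutation_rate = 0.05,
                       planted_up = c("rmsk:AluY" = 2, "rmsk:AluSx" = 2),
                       dispersion = 0.2,
                       libsize_sd = 0.3,
                       covariate_effects = c(age = 0.1, gender = 0.05,
                                             input_volume = 0.1),
                       reads_per_sample = 2000,
                       read_length = 50,
                       frac_background = 0.1,
                       fragment_spec = list(
                         SINE = list(weights = c(0.5, 0.5),
                                     means = c(300, 150), sds = c(20, 15)),
                         LINE = list(weights = 1, means = 258, sds = 60),
                         LTR = list(weights = 1, means = 167, sds = 40)),
                       n_fragments = 2000) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# deterministic per-stage sub-seed, kept below 2^31
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.numeric(seed) * 7919 + h) %% 2147483647
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_dna <- function(seq, rate) {
  bases <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(bases)) < rate
  if (any(hit)) {
    bases[hit] <- vapply(bases[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1)
    }, "")
  }
  paste(bases, collapse = "")
}

#' Generate a toy genome with planted repeat instances and genes
#'
#' Lays out toy genes and mutated copies of per-subfamily consensus
#' sequences (on both strands) along a random background chromosome, at
#' recorded, non-overlapping coordinates, and writes the three annotation
#' inputs the pipeline consumes: a genome FASTA, an rmsk-dialect TSV and a
#' GENCODE-dialect GTF. Byte-identical outputs for identical seeds.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed); when `NULL` nothing is
#'   written and only the in-memory truth is returned.
#' @return List with `genome` (DNAStringSet), `consensus` (per subfamily),
#'   `rmsk` (instance table), `genes` (gene table), and the written `paths`.
#' @export
make_toy_genome <- function(cfg, dir = NULL) {
  set.seed(stage_seed(cfg$seed, "genome"))
  gap <- 200L
  cursor <- gap
  gene_rows <- list()
  gtf_lines <- character(0)
  for (g in seq_len(cfg$n_genes)) {
    len <- sample(400:1500, 1)
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("GENE%04d", g)
    biotype <- if (g %% 4 == 0) "lncRNA" else "protein_coding"
    ntx <- sample(1:3, 1)
    start0 <- cursor
    end0 <- cursor + len
    gtf_lines <- c(gtf_lines, sprintf(
      'chrT\ttoy\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_type "%s"; gene_name "%s";',
      start0 + 1, end0, strand, gid, biotype, gid))
    for (t in seq_len(ntx)) {
      gtf_lines <- c(gtf_lines, sprintf(
        'chrT\ttoy\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.t%d";',
        start0 + 1, end0, strand, gid, gid, t))
    }
    gene_rows[[g]] <- data.frame(gene_id = gid, biotype = biotype,
                                 start = start0, end = end0,
                                 strand = strand, n_tx = ntx,
                                 stringsAsFactors = FALSE)
    cursor <- end0 + gap
  }
  consensus <- lapply(cfg$subfamilies, function(s) random_dna(s$length))
  rmsk_rows <- list()
  inst_seqs <- list()
  for (nm in names(cfg$subfamilies)) {
    s <- cfg$subfamilies[[nm]]
    for (i in seq_len(s$n_instances)) {
      strand <- if (i %% 2 == 0) "-" else "+"
      seq <- mutate_dna(consensus[[nm]], cfg$mutation_rate)
      start0 <- cursor
      end0 <- cursor + nchar(seq)
      rmsk_rows[[length(rmsk_rows) + 1]] <- data.frame(
        genoName = "chrT", genoStart = start0, genoEnd = end0,
        strand = strand, repName = nm, repClass = s$superfamily,
        repFamily = s$family, stringsAsFactors = FALSE)
      inst_seqs[[length(inst_seqs) + 1]] <- list(start = start0,
                                                 seq = seq, strand = strand)
      cursor <- end0 + gap
    }
  }
  genome_len <- cursor + gap
  chrom <- strsplit(random_dna(genome_len), "")[[1]]
  place <- function(start0, seq, strand) {
    s <- if (strand == "-") {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    } else seq
    chrom[(start0 + 1):(start0 + nchar(s))] <<- strsplit(s, "")[[1]]
  }
  for (ins in inst_seqs) place(ins$start, ins$seq, ins$strand)
  genome <- Biostrings::DNAStringSet(paste(chrom, collapse = ""))
  names(genome) <- "chrT"
  rmsk <- do.call(rbind, rmsk_rows)
  genes <- do.call(rbind, gene_rows)

  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  rmsk = file.path(dir, "rmsk.tsv"),
                  gtf = file.path(dir, "genes.gtf"))
    Biostrings::writeXStringSet(genome, paths$genome)
    utils::write.table(rmsk, paths$rmsk, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    writeLines(gtf_lines, paths$gtf)
  }
  list(genome = genome, consensus = consensus, rmsk = rmsk,
       genes = genes, gtf_lines = gtf_lines, paths = paths)
}

#' Exact-match toy quantifier
#'
#' Assigns each read to every reference unit that contains it as an exact
#' substring (strand-resolved reference sequences, forward matching only).
#' Multi-hit reads are split fractionally and equally across their hits;
#' reads matching nothing count toward `total_input_reads` only.
#'
#' @param reads Character vector of read sequences.
#' @param reference Named [Biostrings::DNAStringSet] of unit sequences
#'   (e.g. from [extract_sequences()]).
#' @param sample_id Sample identifier for the resulting table.
#' @return A `QuantTable` with one row per reference unit.
#' @export
toy_quantify <- function(reads, reference, sample_id = "sample") {
  stopifnot(length(reads) > 0, length(reference) > 0)
  hits_per_read <- integer(length(reads))
  counts <- stats::setNames(numeric(length(reference)), names(reference))
  widths <- nchar(reads)
  if (length(unique(widths)) == 1) {
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads))
    hit_lists <- Biostrings::vwhichPDict(pd, reference)  # per-unit read idx
    for (u in seq_along(reference)) {
      idx <- hit_lists[[u]]
      hits_per_read[idx] <- hits_per_read[idx] + 1L
    }
    for (u in seq_along(reference)) {
      idx <- hit_lists[[u]]
      if (length(idx) > 0) counts[u] <- sum(1 / hits_per_read[idx])
    }
  } else {
    for (r in seq_along(reads)) {
      hit <- which(Biostrings::vcountPattern(reads[r], reference) > 0)
      hits_per_read[r] <- length(hit)
      if (length(hit) > 0) counts[hit] <- counts[hit] + 1 / length(hit)
    }
  }
  quant_table(unit_id = names(reference),
              num_reads = unname(counts),
              length = Biostrings::width(reference),
              sample_id = sample_id,
              total_input_reads = length(reads))
}

# expected per-unit read weights for one sample, on the raw scale
unit_weights <- function(catalog, base_expr, is_case, planted_up) {
  feat_expr <- base_expr
  if (is_case && length(planted_up) > 0) {
    idx <- match(names(planted_up), names(feat_expr))
    ok <- !is.na(idx)
    feat_expr[idx[ok]] <- feat_expr[idx[ok]] * 2^unname(planted_up[ok])
  }
  map <- catalog$unit_map
  per_feat_units <- table(map$feature_id)
  w <- feat_expr[map$feature_id] / as.numeric(per_feat_units[map$feature_id])
  stats::setNames(unname(w), map$unit_id)
}

#' Simulate per-sample read sets from a toy genome
#'
#' Draws exact-substring reads from catalog unit sequences under a
#' log-normal baseline expression model with planted disease enrichment,
#' plus a fraction of unassignable background reads from intergenic
#' sequence. Library sizes are log-normal around `cfg$reads_per_sample`.
#'
#' @param truth Output of [make_toy_genome()].
#' @param catalog `FeatureCatalog` built from the toy annotations.
#' @param cfg A [sim_config()].
#' @return List with `reads` (per-sample character vectors), `metadata`
#'   (`sample_id`, `condition`, `age`, `gender`, `input_volume`, `stage`),
#'   and `unit_seqs` (the reference `DNAStringSet`).
#' @export
simulate_cohort_reads <- function(truth, catalog, cfg) {
  set.seed(stage_seed(cfg$seed, "reads"))
  unit_seqs <- extract_sequences(truth$genome, catalog$units)
  n <- cfg$n_healthy + cfg$n_case
  condition <- rep(c("healthy", "disease"), c(cfg$n_healthy, cfg$n_case))
  meta <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    condition = condition,
    age = round(stats::rnorm(n, 60, 10)),
    gender = sample(c("F", "M"), n, replace = TRUE),
    input_volume = round(stats::rnorm(n, 2, 0.4), 2),
    stage = ifelse(condition == "disease",
                   sample(c("I", "II", "III", "IV"), n, replace = TRUE), NA),
    stringsAsFactors = FALSE
  )
  base_expr <- stats::setNames(
    stats::rlnorm(nrow(catalog$features), meanlog = log(10), sdlog = 1),
    catalog$features$feature_id)
  L <- cfg$read_length
  genome_seq <- as.character(truth$genome[[1]])
  unit_char <- stats::setNames(as.character(unit_seqs), names(unit_seqs))
  reads <- vector("list", n)
  for (j in seq_len(n)) {
    w <- unit_weights(catalog, base_expr, condition[j] == "disease",
                      cfg$planted_up)
    # units shorter than the read length cannot yield a read
    w <- w[nchar(unit_char[names(w)]) >= L]
    lib <- max(50, round(stats::rlnorm(1, log(cfg$reads_per_sample),
                                       cfg$libsize_sd)))
    n_bg <- stats::rbinom(1, lib, cfg$frac_background)
    n_fg <- lib - n_bg
    src <- sample(names(w), n_fg, replace = TRUE, prob = w)
    src_seq <- unit_char[src]
    pos <- floor(stats::runif(n_fg) * (nchar(src_seq) - L + 1)) + 1
    rd <- substring(src_seq, pos, pos + L - 1)
    bg_pos <- floor(stats::runif(n_bg) * (nchar(genome_seq) - L + 1)) + 1
    # reversed background slices: effectively never match any unit
    bg <- as.character(Biostrings::reverse(Biostrings::DNAStringSet(
      substring(genome_seq, bg_pos, bg_pos + L - 1))))
    reads[[j]] <- unname(c(rd, bg))
  }
  names(reads) <- meta$sample_id
  list(reads = reads, metadata = meta, unit_seqs = unit_seqs)
}

#' Simulate a negative-binomial count cohort with planted signal
#'
#' Direct count-level simulation (no reads): per-feature log-normal
#' baseline means, log-normal per-sample library scalings, planted
#' condition log2 fold changes on `cfg$planted_up` features, and additive
#' log2-scale covariate effects. Counts are NB with dispersion
#' `cfg$dispersion` (Poisson when 0). Metadata mirrors a clinical sample
#' sheet (`condition`, `age`, `gender`, `input_volume`, `stage`).
#'
#' @param feature_ids Character vector of feature ids (e.g.
#'   `catalog$features$feature_id`, or any synthetic namespace).
#' @param cfg A [sim_config()].
#' @return List with `counts` (`CountMatrix`, raw), `metadata`, `truth`
#'   (per-feature baseline means and planted log2fc).
#' @export
simulate_counts <- function(feature_ids, cfg) {
  set.seed(stage_seed(cfg$seed, "counts"))
  n <- cfg$n_healthy + cfg$n_case
  p <- length(feature_ids)
  condition <- rep(c("healthy", "disease"), c(cfg$n_healthy, cfg$n_case))
  meta <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    condition = condition,
    age = round(stats::rnorm(n, 60, 10)),
    gender = sample(c("F", "M"), n, replace = TRUE),
    input_volume = round(stats::rnorm(n, 2, 0.4), 2),
    stage = ifelse(condition == "disease",
                   sample(c("I", "II", "III", "IV"), n, replace = TRUE), NA),
    stringsAsFactors = FALSE
  )
  base_mu <- stats::rlnorm(p, meanlog = log(50), sdlog = 1)
  lfc <- stats::setNames(rep(0, p), feature_ids)
  planted <- intersect(names(cfg$planted_up), feature_ids)
  lfc[planted] <- cfg$planted_up[planted]
  lib <- stats::rlnorm(n, 0, cfg$libsize_sd)
  age_std <- as.vector(scale(meta$age))
  gen_num <- as.numeric(meta$gender == "M") - 0.5
  vol_std <- as.vector(scale(meta$input_volume))
  ce <- cfg$covariate_effects
  log2mu <- outer(log2(base_mu), rep(1, n)) +
    outer(lfc, as.numeric(condition == "disease")) +
    outer(rep(1, p), ce[["age"]] * age_std +
                     ce[["gender"]] * gen_num +
                     ce[["input_volume"]] * vol_std +
                     log2(lib))
  mu <- 2^log2mu
  counts <- matrix(0, p, n, dimnames = list(feature_ids, meta$sample_id))
  if (cfg$dispersion <= 0) {
    counts[] <- stats::rpois(p * n, lambda = as.vector(mu))
  } else {
    counts[] <- stats::rnbinom(p * n, mu = as.vector(mu),
                               size = 1 / cfg$dispersion)
  }
  list(counts = count_matrix(counts, state = "raw"),
       metadata = meta,
       truth = list(base_mu = stats::setNames(base_mu, feature_ids),
                    log2fc = lfc, lib = lib))
}

#' Simulate aligned long-read fragments with per-group length mixtures
#'
#' Places fragments at planted repeat-instance coordinates, drawing each
#' template length from the configured per-group Gaussian mixture
#' (truncated at 30 nt); the aligned interval is a sub-interval of the
#' source annotation. The default SINE mixture is bimodal (full-length
#' ~300 nt and half-length ~150 nt components).
#'
#' @param units Catalog unit table (`catalog$units`), repeat units only
#'   are used (groups present in `cfg$fragment_spec`).
#' @param cfg A [sim_config()].
#' @return Fragment `data.frame`: `read_id`, `chrom`, `start`, `end`,
#'   `template_length`, `true_group`, `true_unit`.
#' @export
simulate_fragments <- function(units, cfg) {
  set.seed(stage_seed(cfg$seed, "fragments"))
  spec <- cfg$fragment_spec
  units <- units[units$group %in% names(spec), , drop = FALSE]
  stopifnot(nrow(units) > 0)
  # groups configured but absent from the catalog contribute no fragments
  spec <- spec[names(spec) %in% units$group]
  groups <- sample(names(spec), cfg$n_fragments, replace = TRUE)
  rows <- lapply(seq_len(cfg$n_fragments), function(i) {
    g <- groups[i]
    sp <- spec[[g]]
    comp <- sample.int(length(sp$weights), 1, prob = sp$weights)
    len <- max(30, round(stats::rnorm(1, sp$means[comp], sp$sds[comp])))
    pool <- which(units$group == g)
    u <- units[pool[sample.int(length(pool), 1)], ]
    span <- min(len, u$end - u$start)
    off <- sample.int(u$end - u$start - span + 1L, 1) - 1L
    data.frame(read_id = sprintf("frag%06d", i), chrom = u$chrom,
               start = u$start + off, end = u$start + off + span,
               template_length = len, true_group = g,
               true_unit = u$unit_id, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
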