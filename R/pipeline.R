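#' End-to-end pipeline on a synthetic cohort
#'
#' Runs the whole analysis in order on generated data: toy genome ->
#' annotation parsing -> repeat-aware/naive/repeat-alone catalogs ->
#' read simulation -> exact-match quantification -> feature aggregation ->
#' mapping-rate comparison -> normalization, entropy -> training-split
#' differential expression -> feature sets -> elastic-net training with
#' the 90%-specificity threshold -> held-out evaluation. Every stage
#' consumes the previous stage's file or object outputs exactly as a user
#' would drive the exported functions.
#'
#' @param seed Integer seed (drives genome layout, read sampling, split
#'   and CV folds).
#' @param cfg A [sim_config()]; defaults to `sim_config(seed)`.
#' @param dir Working directory for stage outputs; a temporary directory
#'   by default.
#' @param feature_set Which of the eight canonical sets to train on
#'   (default `"de_aware"`).
#' @param alpha_grid,nfolds,target_specificity,train_frac Classifier
#'   protocol settings (defaults: 0..1 by 0.1, 10 folds, 0.90, 0.8).
#' @param covariates Metadata columns adjusted for in the DE model.
#' @param write_outputs Write stage TSV/JSON outputs and a provenance
#'   manifest under `dir`.
#' @return List with `catalogs`, `counts` (aware + naive), `mapping`
#'   (rates and the paired Wilcoxon comparison), `de`, `entropy`,
#'   `feature_sets`, `fit`, `eval`, `split`, `dir`, `manifest`.
#' @export
run_pipeline <- function(seed, cfg = sim_config(seed),
                         dir = tempfile("cfrepeat_run_"),
                         feature_set = "de_aware",
                         alpha_grid = seq(0, 1, by = 0.1),
                         nfolds = 10, target_specificity = 0.90,
                         train_frac = 0.8,
                         covariates = c("age", "gender", "input_volume"),
                         write_outputs = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stages <- character(0)
  note <- function(s) stages <<- c(stages, s)

  truth <- make_toy_genome(cfg, dir = dir)
  note("simulate-genome")
  instances <- parse_rmsk(truth$paths$rmsk)
  genes <- parse_gtf_genes(truth$paths$gtf)
  note("build-annotation")
  cat_aware <- build_catalog(genes, instances, mode = "repeat_aware")
  cat_naive <- build_catalog(genes, instances = NULL, mode = "repeat_naive")

  sim <- simulate_cohort_reads(truth, cat_aware, cfg)
  note("simulate-reads")
  quants <- lapply(names(sim$reads), function(sid) {
    toy_quantify(sim$reads[[sid]], sim$unit_seqs, sample_id = sid)
  })
  note("quantify")
  cm_aware <- aggregate_counts(quants, cat_aware)
  cm_naive <- suppressWarnings(aggregate_counts(quants, cat_naive))
  note("aggregate")

  totals <- attr(cm_aware, "total_input_reads")
  rate_aware <- mapping_rate(attr(cm_aware, "assigned_reads"), totals)
  rate_naive <- mapping_rate(attr(cm_naive, "assigned_reads"), totals)
  mapping <- list(aware = rate_aware, naive = rate_naive,
                  test = wilcoxon_rank_sum(rate_aware, rate_naive,
                                           paired = TRUE))
  note("mapping-rate")

  meta <- sim$metadata
  labels <- stats::setNames(meta$condition == "disease", meta$sample_id)
  split <- stratified_split(labels, train_frac = train_frac, seed = seed)

  cm_train <- count_matrix(as.matrix(cm_aware)[, split$train, drop = FALSE],
                           state = "raw")
  de_train <- nb_wald_test(cm_train, meta, covariates = covariates,
                           condition = "condition", reference = "healthy")
  note("diffexp")

  norm_all <- normalize_counts(cm_aware)
  groups <- feature_groups(cat_aware)
  entropy_tab <- suppressWarnings(shannon_entropy(norm_all, groups))
  note("features")

  sets <- build_feature_sets(norm_all, de_train, split$train,
                             entropy_groups = sort(unique(unname(groups))))
  set <- sets[[feature_set]]
  if (length(set$features) == 0) {
    stop("feature set '", feature_set, "' is empty for this cohort")
  }
  x <- assemble_features(set, norm_all, entropy_tab,
                         sample_ids = meta$sample_id)
  fit <- cv_train(x[split$train, , drop = FALSE], labels[split$train],
                  alpha_grid = alpha_grid, nfolds = nfolds, seed = seed,
                  target_specificity = target_specificity,
                  feature_set = feature_set)
  note("train")
  ev <- evaluate_test(fit, x[split$test, , drop = FALSE], labels[split$test])
  note("evaluate")

  manifest <- NULL
  if (write_outputs) {
    write_unit_map(cat_aware, file.path(dir, "t2g.tsv"))
    write_count_matrix(cm_aware, file.path(dir, "counts_aware.tsv"))
    write_de_table(de_train, file.path(dir, "de_train.tsv"))
    write_model(fit, file.path(dir, "model.json"))
    utils::write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample = names(rate_aware), aware = rate_aware,
                 naive = rate_naive),
      file.path(dir, "mapping_rates.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    files <- c("genome.fa", "rmsk.tsv", "genes.gtf", "t2g.tsv",
               "counts_aware.tsv", "de_train.tsv", "model.json",
               "metadata.tsv", "mapping_rates.tsv")
    manifest <- list(
      seed = seed,
      stages = stages,
      inputs = as.list(tools::md5sum(file.path(dir, files))),
      test_metrics = list(sensitivity = ev$sensitivity,
                          specificity = ev$specificity, auc = ev$auc)
    )
    names(manifest$inputs) <- files
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(catalogs = list(aware = cat_aware, naive = cat_naive),
       counts = list(aware = cm_aware, naive = cm_naive),
       mapping = mapping, de = de_train, entropy = entropy_tab,
       feature_sets = sets, fit = fit, eval = ev, split = split,
       metadata = meta, dir = dir, manifest = manifest)
}
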