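test_that("median-of-ratios size factors match hand-computed values", {
  m <- matrix(c(2, 6, 4, 12), 2, 2,
              dimnames = list(c("F1", "F2"), c("S1", "S2")))
  sf <- size_factors(count_matrix(m, "raw"))
  # geometric means (2.828, 8.485); per-sample ratio medians 1/sqrt2, sqrt2
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-9)

  # identical columns -> equal factors
  m2 <- matrix(rep(c(3, 7, 11), 4), 3, 4,
               dimnames = list(paste0("F", 1:3), paste0("S", 1:4)))
  expect_true(all(abs(diff(size_factors(count_matrix(m2, "raw")))) < 1e-12))

  # scaling one column by 3 triples its factor relative to the others
  # (factors are defined up to a common constant via the geometric means)
  cm <- make_counts(n_feat = 50, n_samp = 6, seed = 1)
  m3 <- as.matrix(cm) + 1  # all-positive so every feature enters the median
  sf1 <- size_factors(count_matrix(m3, "raw"))
  m3[, 2] <- m3[, 2] * 3
  sf2 <- size_factors(count_matrix(m3, "raw"))
  expect_equal(unname((sf2[2] / sf2[1]) / (sf1[2] / sf1[1])), 3,
               tolerance = 1e-9)

  zero <- matrix(c(0, 1, 1, 0), 2, 2,
                 dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(count_matrix(zero, "raw")), "positive counts")
})

test_that("size factors agree with the DESeq2 median-of-ratios reference", {
  skip_if_not_installed("DESeq2")
  cm <- make_counts(n_feat = 100, n_samp = 8, seed = 3)
  ref <- DESeq2::estimateSizeFactorsForMatrix(as.matrix(cm))
  expect_equal(unname(size_factors(cm)), unname(ref), tolerance = 1e-8)
})

test_that("normalization divides by size factors and flips state", {
  cm <- make_counts(seed = 5)
  sf <- size_factors(cm)
  norm <- normalize_counts(cm, sf)
  expect_equal(cm_state(norm), "normalized")
  expect_equal(as.matrix(norm)[, 1], as.matrix(cm)[, 1] / sf[1])
  ones <- normalize_counts(cm, rep(1, ncol(cm)))
  expect_equal(as.matrix(ones), as.matrix(cm))
})

test_that("Shannon entropy matches closed forms and respects bounds", {
  m <- matrix(c(25, 25, 25, 25,
                100, 0, 0, 0,
                50, 25, 25, 0), 4, 3,
              dimnames = list(paste0("F", 1:4), c("uniform", "single", "mix")))
  norm <- count_matrix(m, "normalized")
  grouping <- setNames(rep("SINE", 4), rownames(m))
  H <- shannon_entropy(norm, grouping)
  get <- function(s) H$entropy[H$sample == s]
  expect_equal(get("uniform"), 2.0)          # log2(4)
  expect_equal(get("single"), 0)
  expect_equal(get("mix"), 1.5)              # (.5,.25,.25)

  # zero group total -> NA with warning
  m0 <- cbind(m, empty = 0)
  expect_warning(H0 <- shannon_entropy(count_matrix(m0, "normalized"), grouping),
                 "undefined")
  expect_true(is.na(H0$entropy[H0$sample == "empty"]))
})

test_that("entropy is bounded by log2 of the nonzero group size", {
  set.seed(9)
  for (i in 1:50) {
    k <- sample(2:30, 1)
    counts <- rgamma(k, shape = 0.5)  # random composition
    m <- matrix(counts, k, 1, dimnames = list(paste0("F", 1:k), "s"))
    H <- shannon_entropy(count_matrix(m, "normalized"),
                         setNames(rep("g", k), rownames(m)))
    expect_gte(H$entropy, 0)
    expect_lte(H$entropy, log2(sum(counts > 0)) + 1e-12)
  }
})

test_that("composition fractions sum to one per sample", {
  cm <- make_counts(n_feat = 12, n_samp = 5, seed = 13)
  norm <- normalize_counts(cm, rep(1, 5))
  grouping <- setNames(rep(c("SINE", "LINE", "protein_coding"), each = 4),
                       rownames(cm))
  fr <- composition_fractions(norm, grouping)
  sums <- tapply(fr$fraction, fr$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # all counts in one group -> fraction 1
  m1 <- as.matrix(cm)
  m1[5:12, ] <- 0
  fr1 <- composition_fractions(count_matrix(m1, "normalized"), grouping)
  expect_true(all(fr1$fraction[fr1$group == "SINE"] == 1))
})

test_that("repeat fraction isolates rmsk features", {
  cat <- make_catalog()
  fids <- cat$features$feature_id
  m <- matrix(10, length(fids), 2, dimnames = list(fids, c("S1", "S2")))
  m[startsWith(fids, "rmsk:"), 2] <- 30
  rf <- repeat_fraction(count_matrix(m, "normalized"), cat)
  n_rep <- sum(startsWith(fids, "rmsk:"))
  n_gene <- length(fids) - n_rep
  expect_equal(unname(rf["S1"]), n_rep / length(fids))
  expect_equal(unname(rf["S2"]), 30 * n_rep / (30 * n_rep + 10 * n_gene))
})

test_that("z-scores are centred, scaled and drop constant features", {
  m <- rbind(F1 = c(1, 2, 3), F2 = c(5, 5, 5), F3 = c(10, 20, 60))
  colnames(m) <- paste0("S", 1:3)
  z <- zscore_rows(count_matrix(m, "normalized"))
  expect_equal(cm_state(z), "zscore")
  expect_false("F2" %in% rownames(z))
  expect_equal(unname(z["F1", ]), c(-1, 0, 1))   # sd with n-1 is 1
  expect_equal(unname(rowMeans(z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 1, sd)), c(1, 1), tolerance = 1e-12)
})

test_that("PCA separates planted sample groups and is well-formed", {
  set.seed(21)
  m <- matrix(rnorm(100 * 10, mean = 5), 100, 10)
  m[1:30, 6:10] <- m[1:30, 6:10] + 6   # 30 features separate two clusters
  dimnames(m) <- list(paste0("F", 1:100), paste0("S", 1:10))
  p <- run_pca(count_matrix(m, "log"), rank = 5)
  pc1 <- p$scores[, 1]
  expect_true(max(pc1[1:5]) < min(pc1[6:10]) ||
              min(pc1[1:5]) > max(pc1[6:10]))
  # orthonormal loadings, non-increasing explained variance
  gram <- crossprod(p$loadings)
  expect_equal(gram, diag(ncol(gram)), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1 + 1e-9)
})

test_that("PCA on z-scored input equals PCA with internal scaling", {
  cm <- make_counts(n_feat = 40, n_samp = 8, seed = 31)
  lg <- count_matrix(log2(as.matrix(cm) + 1), "log")
  p_int <- run_pca(lg, rank = 4, scale. = TRUE)
  z <- zscore_rows(lg)
  p_z <- run_pca(z, rank = 4, scale. = FALSE)
  for (k in 1:4) {  # PCs defined up to sign
    expect_equal(abs(p_int$scores[, k]), abs(p_z$scores[, k]),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("sample correlation matrix is symmetric with unit diagonal", {
  cm <- make_counts(n_feat = 30, n_samp = 6, seed = 41)
  cc <- sample_cor(cm)
  expect_equal(diag(cc), setNames(rep(1, 6), colnames(cm)))
  expect_equal(cc, t(cc))
  anti <- matrix(c(1, 2, 3, 3, 2, 1), 3, 2,
                 dimnames = list(paste0("F", 1:3), c("a", "b")))
  expect_equal(sample_cor(count_matrix(anti, "normalized"))["a", "b"], -1)
})

test_that("Wilcoxon wrapper matches the printed exact example and degenerates", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(w$p_value, 0.1)
  expect_warning(wp <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), paired = TRUE),
                 "degenerate")
  expect_equal(wp$p_value, 1)
})

test_that("BH adjustment matches the hand-computed step-up example", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(51)
  p <- runif(30)
  padj <- bh_adjust(p)
  expect_true(all(padj >= p))
  perm <- sample(30)
  expect_equal(bh_adjust(p[perm]), padj[perm])
})

test_that("the eight canonical feature sets assemble with a leakage guard", {
  cat <- make_catalog()
  fids <- cat$features$feature_id
  set.seed(61)
  m <- matrix(rpois(length(fids) * 10, 40), length(fids), 10,
              dimnames = list(fids, paste0("S", 1:10)))
  norm <- count_matrix(m + 0, "normalized")
  train <- paste0("S", 1:8)

  de <- data.frame(feature = fids,
                   padj = c(0.001, 0.5, 0.002, 0.9),
                   stringsAsFactors = FALSE)
  attr(de, "samples") <- train
  groups <- sort(unique(cat$features$group))
  sets <- build_feature_sets(norm, de, train, entropy_groups = groups)

  expect_length(sets, 8)
  expect_setequal(names(sets),
                  c("total_naive", "total_aware", "total_repeat_alone",
                    "de_naive", "de_aware", "de_repeat_alone",
                    "entropy_clade", "entropy_clade_naive"))
  expect_true(all(startsWith(sets$total_repeat_alone$features, "rmsk:")))
  expect_false(any(startsWith(sets$total_naive$features, "rmsk:")))
  expect_setequal(sets$de_aware$features, fids[de$padj < 0.01])
  expect_equal(length(sets$entropy_clade$features), length(groups))

  # provenance covering a test sample must be rejected
  leaky <- de
  attr(leaky, "samples") <- c(train, "S9")
  expect_error(build_feature_sets(norm, leaky, train, groups), "non-training")
  naked <- de
  attr(naked, "samples") <- NULL
  expect_error(build_feature_sets(norm, naked, train, groups), "provenance")
})

test_that("feature-set matrices combine counts and entropy columns", {
  cat <- make_catalog()
  fids <- cat$features$feature_id
  m <- matrix(seq_along(fids), length(fids), 3,
              dimnames = list(fids, c("S1", "S2", "S3"))) + 0
  norm <- count_matrix(m, "normalized")
  ent <- suppressWarnings(shannon_entropy(norm, feature_groups(cat)))
  groups <- sort(unique(cat$features$group))
  de <- data.frame(feature = fids[1], padj = 0.001)
  attr(de, "samples") <- c("S1", "S2")
  sets <- build_feature_sets(norm, de, c("S1", "S2"), groups)
  x <- assemble_features(sets$entropy_clade_naive, norm, ent)
  expect_equal(nrow(x), 3)
  expect_equal(ncol(x), length(groups) + sum(!startsWith(fids, "rmsk:")))
  expect_true(all(paste0("entropy:", groups) %in% colnames(x)))
})
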