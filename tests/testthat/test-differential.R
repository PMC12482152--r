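test_that("median-of-ratios size factors recover proportional depths", {
  m <- matrix(rpois(40, 100), 10, 4)
  counts <- make_counts(cbind(m[, 1], m[, 1], 2 * m[, 1], m[, 2]))
  sf <- estimate_size_factors(counts)
  expect_equal(sf$size_factor[1], sf$size_factor[2])
  expect_equal(sf$size_factor[3] / sf$size_factor[1], 2)

  set.seed(5)
  depths <- c(0.5, 1, 2, 4)
  specs <- gene_specs(sprintf("g%03d", 1:300), biotype = "coding",
                      baseline_mean = exp(runif(300, log(50), log(2000))),
                      dispersion = 0.05)
  design <- study_design(n_replicates = 2,
                         library_size_factors = rep(depths, 2), seed = 31)
  sim <- simulate_counts(specs, design)
  sf <- estimate_size_factors(sim$rnaseq)
  ratios <- sf$size_factor / sf$size_factor[1]
  expect_equal(ratios, depths / depths[1] , tolerance = 0.05)
  expect_error(estimate_size_factors(make_counts(matrix(0, 2, 2))),
               "no gene")
})

test_that("method-of-moments dispersions behave across regimes", {
  meta <- two_cond_meta(2)
  const <- make_counts(matrix(5, 3, 4), libs = meta$library)
  disp <- estimate_dispersions(const, meta,
                               unit_size_factors(meta$library))
  expect_equal(disp$dispersion, rep(1e-8, 3))

  design <- study_design(n_replicates = 200, seed = 8)
  big <- design[design$assay == "rnaseq", ]
  specs <- gene_specs(sprintf("g%d", 1:20), baseline_mean = 200,
                      dispersion = 0)
  sim <- simulate_counts(specs, design)
  disp0 <- estimate_dispersions(sim$rnaseq, big,
                                unit_size_factors(big$library))
  expect_lt(max(disp0$dispersion), 0.01)

  specs1 <- gene_specs(sprintf("g%d", 1:20), baseline_mean = 500,
                       dispersion = 0.1)
  sim1 <- simulate_counts(specs1, study_design(n_replicates = 200, seed = 9))
  disp1 <- estimate_dispersions(sim1$rnaseq, big,
                                unit_size_factors(big$library))
  expect_equal(mean(disp1$dispersion), 0.1, tolerance = 0.03)
  expect_true(all(abs(disp1$dispersion - 0.1) < 0.06))
})

test_that("the Wald test is exact in closed-form cases", {
  meta <- two_cond_meta(4)
  null_counts <- make_counts(matrix(rep(c(3, 9, 12), 8), 3, 8),
                             libs = meta$library)
  res <- nb_wald_test(null_counts, meta, c("control", "stress"),
                      size_factors = unit_size_factors(meta$library))
  expect_equal(res$log2fc, rep(0, 3), tolerance = 1e-9)
  expect_equal(res$pvalue, rep(1, 3), tolerance = 1e-9)
  expect_equal(res$padj, rep(1, 3), tolerance = 1e-9)

  # near-Poisson with unit size factors: the MLE is the ratio of means
  m <- rbind(c(10, 10, 10, 10, 40, 40, 40, 40))
  counts <- make_counts(m, genes = "g1", libs = meta$library)
  res2 <- nb_wald_test(counts, meta, c("control", "stress"),
                       size_factors = unit_size_factors(meta$library),
                       dispersions = poisson_dispersions("g1"))
  expect_equal(res2$log2fc, 2, tolerance = 1e-7)
  expect_true(res2$converged)
})

test_that("the NB coefficient matches a likelihood-grid oracle", {
  meta <- two_cond_meta(2)
  y <- c(13, 21, 48, 65)
  counts <- make_counts(matrix(y, 1), genes = "g1", libs = meta$library)
  alpha <- 0.05
  res <- nb_wald_test(counts, meta, c("control", "stress"),
                      size_factors = unit_size_factors(meta$library),
                      dispersions = tibble::tibble(gene_id = "g1",
                                                   dispersion = alpha))
  # brute force: maximize the NB log-likelihood on a (b0, b1) grid
  grid_ll <- function(b0, b1) {
    mu <- exp(b0 + b1 * c(0, 0, 1, 1))
    sum(dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  }
  search <- function(b0s, b1s) {
    ll <- outer(b0s, b1s, Vectorize(grid_ll))
    best <- arrayInd(which.max(ll), dim(ll))
    c(b0s[best[1]], b1s[best[2]])
  }
  coarse <- search(seq(2, 4, by = 0.02), seq(0.5, 2, by = 0.02))
  fine <- search(seq(coarse[1] - 0.03, coarse[1] + 0.03, by = 2e-4),
                 seq(coarse[2] - 0.03, coarse[2] + 0.03, by = 2e-4))
  expect_equal(res$log2fc * log(2), fine[2], tolerance = 1e-3)
})

test_that("genes with no counts anywhere are excluded from correction", {
  meta <- two_cond_meta(2)
  m <- rbind(c(0, 0, 0, 0), c(10, 12, 30, 28))
  res <- nb_wald_test(make_counts(m, libs = meta$library), meta,
                      c("control", "stress"))
  expect_true(is.na(res$pvalue[1]))
  expect_true(is.na(res$padj[1]))
  expect_false(is.na(res$padj[2]))
})

test_that("TE interaction equals the difference of marginal fits", {
  set.seed(21)
  specs <- gene_specs(sprintf("g%02d", 1:40),
                      baseline_mean = exp(runif(40, log(50), log(1000))),
                      dispersion = 0.02,
                      txn_log2fc = sample(c(-1, 0, 1), 40, TRUE),
                      tln_log2fc = sample(c(-2, 0, 2), 40, TRUE))
  design <- study_design(seed = 77)
  sim <- simulate_counts(specs, design)
  meta_rna <- design[design$assay == "rnaseq", ]
  meta_ribo <- design[design$assay == "riboseq", ]
  te <- te_interaction_test(sim$rnaseq, sim$riboseq, meta_rna, meta_ribo,
                            c("control", "stress"))
  sf <- attr(te, "size_factors")
  disp <- attr(te, "dispersions")
  rna <- nb_wald_test(sim$rnaseq, meta_rna, c("control", "stress"),
                      size_factors = sf, dispersions = disp)
  ribo <- nb_wald_test(sim$riboseq, meta_ribo, c("control", "stress"),
                       size_factors = sf, dispersions = disp)
  expect_equal(te$log2fc, ribo$log2fc - rna$log2fc, tolerance = 1e-6)
})

test_that("TE closed forms: proportional change cancels, excess shows", {
  meta_rna <- two_cond_meta(4, prefix = "rna")
  meta_ribo <- two_cond_meta(4, prefix = "ribo")
  sf <- unit_size_factors(c(meta_rna$library, meta_ribo$library))
  disp <- poisson_dispersions("g1")
  rna <- make_counts(matrix(rep(c(10, 20), each = 4), 1),
                     genes = "g1", libs = meta_rna$library)
  ribo_prop <- make_counts(matrix(rep(c(30, 60), each = 4), 1),
                           genes = "g1", libs = meta_ribo$library)
  te0 <- te_interaction_test(rna, ribo_prop, meta_rna, meta_ribo,
                             c("control", "stress"),
                             size_factors = sf, dispersions = disp)
  expect_equal(te0$log2fc, 0, tolerance = 1e-7)

  ribo_up <- make_counts(matrix(rep(c(10, 80), each = 4), 1),
                         genes = "g1", libs = meta_ribo$library)
  te2 <- te_interaction_test(rna, ribo_up, meta_rna, meta_ribo,
                             c("control", "stress"),
                             size_factors = sf, dispersions = disp)
  expect_equal(te2$log2fc, 3 - 1, tolerance = 1e-7)
})

test_that("BH adjustment matches hand computations and handles NA", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.005, 0.05)), c(0.01, 0.05))
  p <- c(0.01, NA, 0.04)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], bh_adjust(c(0.01, 0.04)))
  expect_error(bh_adjust(c(0.5, 2)), "\\[0, 1\\]")
})

test_that("the significance filter applies strict double thresholds", {
  res <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    log2fc = c(2.63, 0.59, 1.0, -1.5),
    padj = c(0.00, 0.10, 0.001, 0.04)
  )
  sig <- significance_filter(res)
  expect_setequal(sig$gene_id, c("a", "d"))
  # detection in at least one condition is required when sets are given
  sig2 <- significance_filter(res, detected = list(control = "d",
                                                   stress = character()))
  expect_equal(sig2$gene_id, "d")
})

test_that("regulatory classes partition the gene universe", {
  mk <- function(ids, lfc, padj) {
    tibble::tibble(gene_id = ids, log2fc = lfc, padj = padj)
  }
  ids <- c("both", "rna", "ribo", "te", "oppose", "none")
  rna <- mk(ids, c(2, 2, 0.1, 0.2, 2.5, 0), c(0, 0, 0.9, 0.8, 0, 1))
  ribo <- mk(ids, c(2, 0.3, 2, 0.2, 2.1, 0), c(0, 0.7, 0, 0.8, 0, 1))
  te <- mk(ids, c(0.1, -0.2, 0.1, 2, -1.9, 0), c(1, 1, 1, 0.01, 0.01, 1))
  cls <- regulatory_class(rna, ribo, te)
  got <- setNames(as.character(cls$class), cls$gene_id)
  expect_equal(got[["both"]], "both")
  expect_equal(got[["rna"]], "rna_only")
  expect_equal(got[["ribo"]], "ribo_only")
  expect_equal(got[["te"]], "te_only")
  expect_equal(got[["oppose"]], "opposing")
  expect_equal(got[["none"]], "none")
  expect_false(anyNA(cls$class))
})

test_that("Wald estimates agree with an independent NB GLM implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(55)
  meta <- two_cond_meta(4)
  specs <- gene_specs(sprintf("g%02d", 1:25),
                      baseline_mean = exp(runif(25, log(50), log(1000))),
                      dispersion = 0.05,
                      txn_log2fc = sample(c(-2, 0, 2), 25, TRUE))
  sim <- simulate_counts(specs, study_design(seed = 56))
  m <- as.matrix(sim$rnaseq[-1])
  rownames(m) <- sim$rnaseq$gene_id
  colnames(m) <- meta$library
  counts <- make_counts(m, genes = rownames(m), libs = meta$library)
  alpha <- 0.08
  res <- nb_wald_test(counts, meta, c("control", "stress"),
                      size_factors = unit_size_factors(meta$library),
                      dispersions = tibble::tibble(gene_id = rownames(m),
                                                   dispersion = alpha))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = matrix(as.integer(m), nrow(m),
                         dimnames = dimnames(m)),
      colData = data.frame(condition = factor(meta$condition,
                                              c("control", "stress"))),
      design = ~condition)
    DESeq2::sizeFactors(dds) <- rep(1, ncol(m))
    DESeq2::dispersions(dds) <- rep(alpha, nrow(m))
    dds <- DESeq2::nbinomWaldTest(dds)
    ref <- DESeq2::results(dds)
  })
  expect_equal(res$log2fc, ref$log2FoldChange, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(res$se, ref$lfcSE, tolerance = 1e-3, ignore_attr = TRUE)
})
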