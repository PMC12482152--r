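#' Median-of-ratios library size factors
#'
#' For each library j, \eqn{s_j} is the median over genes (restricted to
#' genes with a positive geometric mean across libraries) of
#' \eqn{c_{gj} / \mathrm{geomean}_g}.  Columns that are exact multiples of
#' one another recover the multiples up to a common scale.
#'
#' @param counts Count tibble (`gene_id` + libraries).
#' @return A tibble with `library` and `size_factor`.
#' @export
estimate_size_factors <- function(counts) {
  m <- counts_to_matrix(counts)
  loggeo <- rowMeans(log(m))
  use <- is.finite(loggeo)
  if (!any(use)) abort("no gene has positive counts in every library")
  lr <- log(m[use, , drop = FALSE]) - loggeo[use]
  tibble(library = colnames(m),
         size_factor = unname(exp(apply(lr, 2, median))))
}

#' Per-gene method-of-moments NB dispersions
#'
#' On size-factor-normalized counts, computes within each condition the
#' moment estimate \eqn{\hat\alpha_c = (s_c^2 - \bar\mu_c)/\bar\mu_c^2},
#' pools across conditions weighting by residual degrees of freedom
#' \eqn{n_c - 1}, truncates at zero and floors the result at `1e-8` so
#' degenerate genes (e.g. constant replicates) behave as near-Poisson.
#'
#' @param counts Count tibble.
#' @param meta Library metadata (`library`, `condition`).
#' @param size_factors Optional tibble from [estimate_size_factors()]
#'   (estimated from `counts` when omitted).
#' @return A tibble with `gene_id` and `dispersion`.
#' @export
estimate_dispersions <- function(counts, meta, size_factors = NULL) {
  check_library_metadata(meta, counts)
  m <- counts_to_matrix(counts)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  sf <- setNames(size_factors$size_factor, size_factors$library)[colnames(m)]
  k <- sweep(m, 2, sf, "/")
  conds <- unique(meta$condition)
  num <- 0
  den <- 0
  for (cond in conds) {
    libs <- meta$library[meta$condition == cond]
    if (length(libs) < 2) abort("at least 2 replicates per condition needed")
    kc <- k[, libs, drop = FALSE]
    mu <- rowMeans(kc)
    v <- apply(kc, 1, var)
    a <- if_else(mu > 0, (v - mu) / mu^2, 0)
    w <- length(libs) - 1
    num <- num + w * a
    den <- den + w
  }
  tibble(gene_id = rownames(m),
         dispersion = unname(pmax(num / den, 1e-8)))
}

# Per-gene NB log-linear GLM fitted by iteratively reweighted least squares
# with log link, fixed dispersion alpha and offsets log(s_j).
fit_nb_glm <- function(y, X, offset, alpha, max_iter = 100, tol = 1e-12) {
  eta <- log(pmax(y, 0.5)) - offset
  beta <- tryCatch(qr.solve(X, eta), error = function(e) rep(0, ncol(X)))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta) + offset
    eta <- pmin(pmax(eta, -30), 30)
    mu <- exp(eta)
    w <- mu / (1 + alpha * mu)
    z <- (eta - offset) + (y - mu) / mu
    XtW <- t(X * w)
    fit <- tryCatch(solve(XtW %*% X, XtW %*% z), error = function(e) NULL)
    if (is.null(fit)) break
    delta <- drop(fit) - beta
    beta <- drop(fit)
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  eta <- pmin(pmax(drop(X %*% beta) + offset, -30), 30)
  mu <- exp(eta)
  w <- mu / (1 + alpha * mu)
  info <- t(X * w) %*% X
  cov <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(X), ncol(X))
  })
  list(beta = beta, se = sqrt(pmax(diag(cov), 0)), mu = mu,
       converged = converged)
}

new_deres <- function(df, contrast, size_factors, dispersions, df_resid) {
  attr(df, "contrast") <- contrast
  attr(df, "size_factors") <- size_factors
  attr(df, "dispersions") <- dispersions
  attr(df, "df_resid") <- df_resid
  class(df) <- c("ribote_deres", class(df))
  df
}

#' Negative-binomial Wald test of a two-condition contrast
#'
#' Fits, per gene, the NB log-linear model
#' \eqn{\log \mu_{gj} = \beta_0 + \beta_1 \,[\mathrm{condition}_j =
#' \mathrm{stress}] + \log s_j} by IRLS with the gene's dispersion held
#' fixed, and tests \eqn{\beta_1 = 0} with the Wald statistic
#' \eqn{\beta_1 / SE(\beta_1)}.  `log2fc` is \eqn{\beta_1 / \ln 2}.
#'
#' Because the per-gene dispersion is estimated from few replicates and then
#' plugged in, the Wald statistic is referred by default to a t distribution
#' with the dispersion estimator's residual degrees of freedom
#' \eqn{\sum_c (n_c - 1)}; a standard-normal reference (appropriate when
#' dispersions are known or replicates many) is available via
#' `p_reference = "normal"`.
#'
#' Genes with all-zero counts are reported with `NA` statistics and are
#' excluded from the multiple-testing correction; genes whose IRLS fit does
#' not converge (e.g. a condition with no counts at all) are flagged
#' `converged = FALSE` rather than dropped.
#'
#' @param counts Count tibble for one assay.
#' @param meta Library metadata (`library`, `condition`).
#' @param contrast Length-2 character: reference condition then test
#'   condition.  Defaults to the metadata's condition order.
#' @param size_factors,dispersions Optional precomputed tibbles; estimated
#'   from `counts` when omitted.
#' @param p_reference `"t"` (default) or `"normal"`.
#' @return A `ribote_deres` tibble: `gene_id`, `contrast`, `base_mean`
#'   (mean of normalized counts), `log2fc`, `se` (log2 scale), `stat`,
#'   `pvalue`, `padj`, `converged`.
#' @export
nb_wald_test <- function(counts, meta, contrast = NULL,
                         size_factors = NULL, dispersions = NULL,
                         p_reference = c("t", "normal")) {
  p_reference <- arg_match(p_reference)
  check_library_metadata(meta, counts)
  if (is.null(contrast)) contrast <- unique(meta$condition)
  if (length(contrast) != 2) abort("contrast must name two conditions")
  meta <- meta[meta$condition %in% contrast, ]
  counts <- counts[c("gene_id", meta$library)]
  tab <- table(meta$condition)
  if (any(tab < 2)) abort("at least 2 replicates per condition required")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(counts, meta, size_factors)
  }
  m <- counts_to_matrix(counts)
  sf <- setNames(size_factors$size_factor, size_factors$library)[colnames(m)]
  alpha <- setNames(dispersions$dispersion, dispersions$gene_id)[rownames(m)]
  X <- cbind(1, as.numeric(meta$condition == contrast[2]))
  offset <- log(sf)
  df_resid <- sum(tab - 1)
  res <- fit_wald(m, X, offset, alpha, 2L, p_reference, df_resid)
  res <- bind_cols(tibble(gene_id = rownames(m),
                          contrast = paste(contrast[2], "vs", contrast[1])),
                   res)
  res$padj <- bh_adjust(res$pvalue)
  new_deres(as_tibble(res), "condition", size_factors, dispersions, df_resid)
}

fit_wald <- function(m, X, offset, alpha, coef_idx, p_reference, df_resid) {
  G <- nrow(m)
  out <- tibble(base_mean = rowMeans(sweep(m, 2, exp(offset), "/")),
                log2fc = NA_real_, se = NA_real_, stat = NA_real_,
                pvalue = NA_real_, converged = NA)
  for (g in seq_len(G)) {
    y <- m[g, ]
    if (all(y == 0)) next
    fit <- fit_nb_glm(y, X, offset, alpha[g])
    b <- fit$beta[coef_idx]
    s <- fit$se[coef_idx]
    out$log2fc[g] <- b / log(2)
    out$se[g] <- s / log(2)
    out$converged[g] <- fit$converged
    if (is.finite(s) && s > 0) {
      stat <- b / s
      out$stat[g] <- stat
      out$pvalue[g] <- if (p_reference == "t") {
        2 * pt(-abs(stat), df = df_resid)
      } else {
        2 * pnorm(-abs(stat))
      }
    }
  }
  out
}

#' Translation-efficiency interaction test
#'
#' Joins the RNA-seq and Ribo-seq count matrices and fits, per gene, the NB
#' model with terms for assay, condition and their interaction,
#' \deqn{\log \mu = \beta_0 + \beta_a A + \beta_c C + \beta_{ac} A C +
#' \log s_j,}
#' where \eqn{A} indicates Ribo-seq and \eqn{C} the stress condition.  The
#' TE log2 fold change is the interaction coefficient
#' \eqn{\beta_{ac}/\ln 2}: the amount by which the Ribo-seq fold change
#' exceeds the RNA-seq fold change.  Size factors are estimated per library
#' on the combined matrix; a single dispersion per gene is shared across the
#' four assay-condition groups (method-of-moments within group, pooled).
#' With this shared dispersion and no shrinkage, the TE estimate equals the
#' difference of the marginal Ribo-seq and RNA-seq estimates.
#'
#' @param rna_counts,ribo_counts Count tibbles over the same gene universe.
#' @param meta_rna,meta_ribo Per-assay library metadata (`library`,
#'   `condition`); library names must be unique across the two assays.
#' @param contrast Reference and test condition.
#' @param size_factors,dispersions Optional precomputed tibbles (combined
#'   libraries / shared per-gene dispersion); estimated when omitted.
#' @param p_reference As in [nb_wald_test()].
#' @return A `ribote_deres` tibble (contrast `"te"`) with the same columns
#'   as [nb_wald_test()].  The combined size factors and shared dispersions
#'   are attached as attributes for reuse in marginal fits.
#' @export
te_interaction_test <- function(rna_counts, ribo_counts, meta_rna, meta_ribo,
                                contrast = NULL, size_factors = NULL,
                                dispersions = NULL,
                                p_reference = c("t", "normal")) {
  p_reference <- arg_match(p_reference)
  if (!identical(sort(rna_counts$gene_id), sort(ribo_counts$gene_id))) {
    abort("RNA and Ribo count matrices must share the same gene set")
  }
  check_library_metadata(meta_rna, rna_counts)
  check_library_metadata(meta_ribo, ribo_counts)
  if (length(intersect(meta_rna$library, meta_ribo$library)) > 0) {
    abort("library names must be unique across assays")
  }
  ribo_counts <- ribo_counts[match(rna_counts$gene_id, ribo_counts$gene_id), ]
  meta <- bind_rows(mutate(meta_rna, assay = "rna"),
                    mutate(meta_ribo, assay = "ribo"))
  if (is.null(contrast)) contrast <- unique(meta$condition)
  meta <- meta[meta$condition %in% contrast, ]
  combined <- left_join(rna_counts, ribo_counts, by = "gene_id")
  combined <- combined[c("gene_id", meta$library)]
  if (is.null(size_factors)) size_factors <- estimate_size_factors(combined)
  group_meta <- mutate(meta,
                       condition = paste(.data$assay, .data$condition))
  if (is.null(dispersions)) {
    dispersions <- estimate_dispersions(combined, group_meta, size_factors)
  }
  m <- counts_to_matrix(combined)
  sf <- setNames(size_factors$size_factor, size_factors$library)[colnames(m)]
  alpha <- setNames(dispersions$dispersion, dispersions$gene_id)[rownames(m)]
  A <- as.numeric(meta$assay == "ribo")
  C <- as.numeric(meta$condition == contrast[2])
  X <- cbind(1, A, C, A * C)
  df_resid <- sum(table(paste(meta$assay, meta$condition)) - 1)
  res <- fit_wald(m, X, log(sf), alpha, 4L, p_reference, df_resid)
  res <- bind_cols(tibble(gene_id = rownames(m), contrast = "te"), res)
  res$padj <- bh_adjust(res$pvalue)
  new_deres(as_tibble(res), "te", size_factors, dispersions, df_resid)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()]; `NA`/`NaN` inputs
#' propagate unchanged and are excluded from the number of tests.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  out <- pvalues
  out[ok] <- p.adjust(pvalues[ok], method = "BH")
  out
}

#' Significance filter for differential results
#'
#' A gene qualifies iff `padj < alpha` and `|log2fc| > lfc_min` (both
#' strict) and, when detection sets are supplied, the gene was detected in
#' at least one condition.  A printed adjusted p-value of "0.00" therefore
#' qualifies and a log2 fold change of exactly 1 does not.
#'
#' @param results A differential-result data frame with `gene_id`,
#'   `log2fc`, `padj`.
#' @param alpha Adjusted-p cutoff (strict), default 0.05.
#' @param lfc_min Absolute log2-fold-change cutoff (strict), default 1.
#' @param detected Optional character vector, or list of character vectors
#'   (one per condition), of detected gene ids; `NULL` skips the detection
#'   requirement.
#' @return The qualifying rows of `results`.
#' @export
significance_filter <- function(results, alpha = 0.05, lfc_min = 1,
                                detected = NULL) {
  stopifnot(all(c("gene_id", "log2fc", "padj") %in% names(results)))
  keep <- !is.na(results$padj) & results$padj < alpha &
    !is.na(results$log2fc) & abs(results$log2fc) > lfc_min
  if (!is.null(detected)) {
    dset <- unique(unlist(detected))
    keep <- keep & results$gene_id %in% dset
  }
  as_tibble(results[keep, ])
}

#' Partition genes into transcriptional/translational regulatory classes
#'
#' Combines the RNA-seq, Ribo-seq and TE calls into seven mutually
#' exclusive, exhaustive classes.  TE-significant genes split on whether the
#' transcript-level change was substantial (`|log2fc(rna)| > lfc_min`):
#' if so they are `te_and_transcriptional`, or `opposing` when the RNA and
#' TE fold changes point in opposite directions (both exceeding `lfc_min`
#' in magnitude) — the signature of a transcriptionally induced gene whose
#' translation is simultaneously repressed; otherwise `te_only`.  Genes not
#' TE-significant fall into `both`, `rna_only`, `ribo_only` or `none` from
#' the marginal calls.
#'
#' @param rna_results,ribo_results,te_results `ribote_deres` tibbles over
#'   one gene universe.
#' @param alpha,lfc_min Strict thresholds, as in [significance_filter()].
#' @param detected Optional detection sets passed through to
#'   [significance_filter()].
#' @return A tibble with `gene_id` and `class`.
#' @export
regulatory_class <- function(rna_results, ribo_results, te_results,
                             alpha = 0.05, lfc_min = 1, detected = NULL) {
  universe <- union(rna_results$gene_id,
                    union(ribo_results$gene_id, te_results$gene_id))
  sig <- function(res) {
    significance_filter(res, alpha, lfc_min, detected)$gene_id
  }
  rna_sig <- sig(rna_results)
  ribo_sig <- sig(ribo_results)
  te_sig <- sig(te_results)
  rna_lfc <- setNames(rna_results$log2fc, rna_results$gene_id)[universe]
  te_lfc <- setNames(te_results$log2fc, te_results$gene_id)[universe]
  rna_big <- !is.na(rna_lfc) & abs(rna_lfc) > lfc_min
  opposite <- rna_big & !is.na(te_lfc) & abs(te_lfc) > lfc_min &
    sign(rna_lfc) != sign(te_lfc)
  cls <- case_when(
    universe %in% te_sig & opposite ~ "opposing",
    universe %in% te_sig & rna_big ~ "te_and_transcriptional",
    universe %in% te_sig ~ "te_only",
    universe %in% rna_sig & universe %in% ribo_sig ~ "both",
    universe %in% rna_sig ~ "rna_only",
    universe %in% ribo_sig ~ "ribo_only",
    .default = "none"
  )
  tibble(gene_id = universe,
         class = factor(cls, levels = c(
           "rna_only", "ribo_only", "both", "te_only",
           "te_and_transcriptional", "opposing", "none")))
}
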