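#' Overlap of predicted sRNA targets with differential translation
#'
#' Keeps high-confidence interaction predictions (`interaction_pvalue <
#' p_max`, strict) and counts, per sRNA, how many predicted mRNA targets
#' were differentially translated — significant in the Ribo-seq contrast
#' *or* the TE contrast under the same strict thresholds as
#' [significance_filter()].  Targets absent from the differential results
#' (e.g. excluded for low expression) count as not differential, with a
#' warning, rather than shrinking the denominator.
#'
#' @param predictions Tibble with `srna_id`, `target_gene_id`,
#'   `interaction_pvalue` (a `pvalue` column is accepted as an alias);
#'   duplicate (srna, target) pairs are collapsed to their smallest p-value.
#' @param ribo_results,te_results Differential-result data frames
#'   (`gene_id`, `log2fc`, `padj`).
#' @param p_max Strict high-confidence cutoff on the interaction p-value.
#' @param alpha,lfc_min,detected Passed to [significance_filter()].
#' @return A tibble per sRNA: `srna_id`, `n_targets`, `n_differential`,
#'   `fraction` (`NA` when `n_targets` is 0).
#' @export
target_overlap <- function(predictions, ribo_results, te_results,
                           p_max = 0.01, alpha = 0.05, lfc_min = 1,
                           detected = NULL) {
  if (!"interaction_pvalue" %in% names(predictions) &&
      "pvalue" %in% names(predictions)) {
    predictions <- rename(predictions, interaction_pvalue = "pvalue")
  }
  stopifnot(all(c("srna_id", "target_gene_id", "interaction_pvalue") %in%
                  names(predictions)))
  hc <- predictions %>%
    group_by(.data$srna_id, .data$target_gene_id) %>%
    summarise(interaction_pvalue = min(.data$interaction_pvalue),
              .groups = "drop") %>%
    filter(.data$interaction_pvalue < p_max)
  diff_set <- union(
    significance_filter(ribo_results, alpha, lfc_min, detected)$gene_id,
    significance_filter(te_results, alpha, lfc_min, detected)$gene_id
  )
  known <- union(ribo_results$gene_id, te_results$gene_id)
  missing <- setdiff(hc$target_gene_id, known)
  if (length(missing) > 0) {
    warn(sprintf(
      "%d predicted target(s) absent from the differential results; counted as not differential",
      length(missing)))
  }
  out <- hc %>%
    group_by(.data$srna_id) %>%
    summarise(
      n_targets = dplyr::n(),
      n_differential = sum(.data$target_gene_id %in% diff_set),
      .groups = "drop"
    ) %>%
    mutate(fraction = if_else(.data$n_targets > 0,
                              .data$n_differential / .data$n_targets,
                              NA_real_))
  class(out) <- c("ribote_overlap", class(out))
  out
}

#' Functional-category enrichment of a differential gene set
#'
#' For each category, the fold enrichment is \eqn{(k/n) / (K/N)} where
#' \eqn{k} is the number of study genes mapped to the category, \eqn{n} the
#' total number of mapped study genes, and \eqn{K}, \eqn{N} the analogous
#' background totals (the "total hits per group" convention of
#' homology-based GO mappers, where only genes with at least one category
#' assignment count).  Significance is a two-sided Fisher exact test on the
#' 2x2 table (in/out of category x study/rest-of-background), with
#' Benjamini-Hochberg correction across categories.  Categories with no
#' background hits are skipped with a message.
#'
#' @param study_set Character vector of study gene ids (must be a subset of
#'   the background).
#' @param background_set Character vector of background gene ids.
#' @param category_map Tibble with `gene_id` and `category` (one row per
#'   assignment; genes may map to several categories).
#' @return A tibble per category: `category`, `k`, `n`, `K`, `N`, `fold`,
#'   `pvalue`, `fdr`.
#' @export
#' @examples
#' category_enrichment(
#'   study_set = c("g1", "g2"),
#'   background_set = paste0("g", 1:20),
#'   category_map = tibble::tibble(gene_id = paste0("g", 1:6),
#'                                 category = rep(c("redox", "other"), 3))
#' )
category_enrichment <- function(study_set, background_set, category_map) {
  if (!all(study_set %in% background_set)) {
    abort("study_set must be a subset of background_set")
  }
  stopifnot(all(c("gene_id", "category") %in% names(category_map)))
  map <- distinct(category_map, .data$gene_id, .data$category) %>%
    filter(.data$gene_id %in% background_set)
  n <- dplyr::n_distinct(map$gene_id[map$gene_id %in% study_set])
  N <- dplyr::n_distinct(map$gene_id)
  if (N == 0) abort("no background gene maps to any category")
  cats <- unique(category_map$category)
  rows <- purrr::map(cats, function(cat) {
    in_cat <- unique(map$gene_id[map$category == cat])
    K <- length(in_cat)
    if (K == 0) {
      inform(paste("category with no background hits skipped:", cat))
      return(NULL)
    }
    k <- sum(in_cat %in% study_set)
    tab <- matrix(c(k, n - k, K - k, (N - n) - (K - k)), nrow = 2)
    tibble(category = cat, k = k, n = n, K = K, N = N,
           fold = (k / n) / (K / N),
           pvalue = fisher.test(tab, alternative = "two.sided")$p.value)
  })
  out <- bind_rows(rows)
  out$fdr <- bh_adjust(out$pvalue)
  out
}
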