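#' Build a footprint-profile matrix for coding-potential clustering
#'
#' Converts per-gene footprint length histograms (counts summed across all
#' biological replicates of one condition) to percentage profiles, marks
#' genes below the read-count threshold as excluded, and appends the pooled
#' "all CDS" profile computed by summing counts over every coding reference
#' gene before percentage conversion (so deeply sequenced genes carry more
#' weight than shallow ones).
#'
#' @param histograms Length-count tibble (`gene_id` plus one column per
#'   length) for one condition.
#' @param classes Tibble mapping `gene_id` to `class`: `"coding"`,
#'   `"rrna"`, `"trna"`, `"other_noncoding"`, or `"srna"`.
#' @param min_reads Minimum total reads (summed across replicates) for a
#'   profile to enter the clustering; 65 is the calibrated default below
#'   which footprint-length profiles are too noisy to classify reliably.
#'   The comparison is `total < min_reads` excludes, so a gene at exactly
#'   the threshold is kept.
#' @return A `ribote_profiles` tibble: `gene_id`, `reference_class`
#'   (`coding_ref`, `noncoding_ref`, `srna_query`, `pooled_cds`), `ref_type`
#'   (the fine class), `total_reads`, `excluded`, then one percentage column
#'   per length (percentages sum to 100 for profiles with reads).
#' @export
build_profile_matrix <- function(histograms, classes, min_reads = 65) {
  m <- counts_to_matrix(histograms[setdiff(names(histograms), "total")])
  cls <- setNames(classes$class, classes$gene_id)[rownames(m)]
  if (anyNA(cls)) abort("every histogram gene needs a class")
  if (!any(cls == "coding")) abort("empty coding reference set")
  totals <- rowSums(m)
  pooled <- colSums(m[cls == "coding", , drop = FALSE])
  m <- rbind(m, pooled_cds = pooled)
  totals <- c(totals, pooled_cds = sum(pooled))
  pct <- m / if_else(totals > 0, totals, 1) * 100
  pct[totals == 0, ] <- NA_real_
  ref <- c(case_when(
    cls == "coding" ~ "coding_ref",
    cls == "srna" ~ "srna_query",
    .default = "noncoding_ref"
  ), "pooled_cds")
  out <- bind_cols(
    tibble(gene_id = rownames(m),
           reference_class = ref,
           ref_type = c(as.character(cls), "pooled_cds"),
           total_reads = unname(totals),
           excluded = unname(totals) < min_reads | !is.finite(rowSums(pct))),
    as_tibble(pct)
  )
  attr(out, "min_reads") <- min_reads
  class(out) <- c("ribote_profiles", class(out))
  out
}

#' Hierarchically cluster footprint-length profiles
#'
#' Agglomerative clustering (default Euclidean distance, complete linkage —
#' the defaults of the clustered-heatmap tools this analysis mirrors) of all
#' included profiles, then the tree is cut at k = 2, 3, ... until no cluster
#' contains both an rRNA reference and a coding reference (the pooled CDS
#' profile counts as coding).  tRNA and other structural RNAs are not
#' required to separate.  If no k up to the number of profiles separates
#' them, `separation_achieved` is `FALSE`.
#'
#' @param profiles A `ribote_profiles` tibble.
#' @param distance Distance measure for [stats::dist()].
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return A `ribote_clustering` list: `k`, `assignments` (tibble `gene_id`,
#'   `cluster`), `hclust`, `separation_achieved`.
#' @export
cluster_profiles <- function(profiles, distance = "euclidean",
                             linkage = "complete") {
  inc <- profiles[!profiles$excluded, ]
  if (nrow(inc) < 2) abort("need at least 2 included profiles to cluster")
  if (!any(inc$reference_class %in% c("coding_ref", "pooled_cds")) ||
      !any(inc$reference_class == "noncoding_ref")) {
    abort("clustering needs at least one coding and one noncoding reference")
  }
  pct <- as.matrix(inc[setdiff(names(inc), c(
    "gene_id", "reference_class", "ref_type", "total_reads", "excluded"))])
  rownames(pct) <- inc$gene_id
  d <- dist(pct, method = distance)
  h <- hclust(d, method = linkage)
  is_coding <- inc$reference_class %in% c("coding_ref", "pooled_cds")
  is_rrna <- inc$ref_type == "rrna"
  # identical coding and rRNA profiles can be split by a tree cut but not
  # meaningfully separated
  dm <- as.matrix(d)
  separable <- !any(dm[is_coding, is_rrna, drop = FALSE] == 0)
  k_found <- NA_integer_
  assign <- NULL
  if (separable) {
    for (k in 2:nrow(inc)) {
      ct <- cutree(h, k = k)
      mixed <- tapply(seq_along(ct), ct, function(i) {
        any(is_coding[i]) && any(is_rrna[i])
      })
      if (!any(mixed)) {
        k_found <- k
        assign <- ct
        break
      }
    }
  }
  sep <- !is.na(k_found)
  if (!sep) {
    k_found <- nrow(inc)
    assign <- cutree(h, k = k_found)
  }
  structure(list(
    k = k_found,
    assignments = tibble(gene_id = inc$gene_id,
                         cluster = unname(assign)),
    hclust = h,
    separation_achieved = sep
  ), class = "ribote_clustering")
}

#' Call sRNA coding potential from a profile clustering
#'
#' An sRNA is `coding_like` iff its cluster contains at least one coding
#' reference profile (the pooled CDS profile counts), `not_coding_like`
#' otherwise; sRNAs excluded for insufficient reads are called
#' `insufficient_reads` with `cluster = NA` — the per-condition analogue of
#' a Yes/No/NA coding-cluster column.
#'
#' @param clustering A [cluster_profiles()] result with
#'   `separation_achieved = TRUE` (otherwise the call is refused).
#' @param profiles The `ribote_profiles` tibble that was clustered.
#' @param condition Optional condition label copied into the output.
#' @return A tibble: `gene_id`, `condition`, `total_reads`, `cluster`,
#'   `call`.
#' @export
classify_srnas <- function(clustering, profiles, condition = NA_character_) {
  if (!isTRUE(clustering$separation_achieved)) {
    abort("clustering did not separate rRNA from coding references; refusing to call")
  }
  asg <- setNames(clustering$assignments$cluster,
                  clustering$assignments$gene_id)
  inc <- profiles[!profiles$excluded, ]
  coding_clusters <- unique(asg[inc$gene_id[
    inc$reference_class %in% c("coding_ref", "pooled_cds")]])
  q <- profiles[profiles$reference_class == "srna_query", ]
  tibble(
    gene_id = q$gene_id,
    condition = condition,
    total_reads = q$total_reads,
    cluster = unname(asg[q$gene_id]),
    call = case_when(
      q$excluded ~ "insufficient_reads",
      asg[q$gene_id] %in% coding_clusters ~ "coding_like",
      .default = "not_coding_like"
    )
  )
}

#' Calibrate the minimum read-count threshold for reliable classification
#'
#' Re-runs the build/cluster/classify sequence at each candidate threshold,
#' keeping only profiles with at least that many total reads, and returns
#' the smallest candidate at which every positive-control sRNA (sRNAs with
#' annotated smORFs) that survives the threshold is classified
#' `coding_like`.  If no candidate achieves this, the largest candidate is
#' returned with a warning.  This reproduces the logic by which a read-count
#' floor is chosen so that low-coverage positives, which cluster
#' erratically, fall below it.
#'
#' @param histograms,classes As in [build_profile_matrix()].
#' @param positives Character vector of positive-control sRNA ids
#'   (non-empty).
#' @param candidate_thresholds Ascending integer candidates.
#' @return The selected integer threshold.
#' @export
calibrate_min_count <- function(histograms, classes, positives,
                                candidate_thresholds) {
  if (length(positives) == 0) abort("positives must be non-empty")
  candidate_thresholds <- sort(candidate_thresholds)
  totals <- rowSums(counts_to_matrix(
    histograms[setdiff(names(histograms), "total")]))
  if (all(totals[positives] < min(candidate_thresholds), na.rm = TRUE)) {
    abort("all positives fall below every candidate threshold")
  }
  for (t in candidate_thresholds) {
    profiles <- build_profile_matrix(histograms, classes, min_reads = t)
    clustering <- tryCatch(cluster_profiles(profiles),
                           error = function(e) NULL)
    if (is.null(clustering) || !clustering$separation_achieved) next
    calls <- classify_srnas(clustering, profiles)
    pos <- calls[calls$gene_id %in% positives &
                   calls$call != "insufficient_reads", ]
    if (nrow(pos) > 0 && all(pos$call == "coding_like")) {
      return(as.integer(t))
    }
  }
  warn("no candidate threshold classified all surviving positives as coding; returning the largest")
  as.integer(max(candidate_thresholds))
}
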