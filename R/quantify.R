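#' Transcripts-per-million normalization
#'
#' \eqn{TPM_g = 10^6 (c_g/\ell_g) / \sum_h (c_h/\ell_h)} per library, using
#' the annotated gene length \eqn{\ell_g} in nt (no effective-length
#' correction).  Every library column of the result sums to one million; a
#' library with no counts at all yields an all-zero column with a warning.
#'
#' @param counts Count tibble (`gene_id` plus one column per library).
#' @param gene_lengths Either a tibble with `gene_id` and `length_nt`
#'   columns (e.g. the annotation) or a named numeric vector of lengths.
#' @return A tibble of the same shape as `counts` holding TPM values.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = c("A", "B"), lib1 = c(10, 30))
#' compute_tpm(counts, c(A = 1000, B = 1500))
compute_tpm <- function(counts, gene_lengths) {
  m <- counts_to_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative")
  len <- if (is.data.frame(gene_lengths)) {
    setNames(gene_lengths$length_nt, gene_lengths$gene_id)[rownames(m)]
  } else {
    gene_lengths[rownames(m)]
  }
  if (anyNA(len) || any(len <= 0)) {
    abort("every gene needs a positive length")
  }
  rate <- m / len
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warn(paste("library with no counts yields all-zero TPM:",
               paste(colnames(m)[zero], collapse = ", ")))
    denom[zero] <- 1
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  matrix_to_counts(tpm)
}

#' Detection filter on mean TPM
#'
#' A gene counts as detected in a condition iff its mean TPM across that
#' condition's replicate libraries is strictly greater than `threshold`
#' (default 10 TPM, the conventional minimum detection cutoff averaged
#' across biological replicates; a gene sitting exactly at the threshold is
#' not detected).
#'
#' @param tpm TPM tibble from [compute_tpm()].
#' @param meta Library metadata tibble (`library`, `condition`, ...).
#' @param condition Condition label to average over.
#' @param threshold Strict detection cutoff in TPM.
#' @return Character vector of detected gene ids.
#' @export
detection_filter <- function(tpm, meta, condition, threshold = 10) {
  check_library_metadata(meta)
  libs <- meta$library[meta$condition == condition]
  if (length(libs) == 0) abort(paste("no replicates for condition", condition))
  m <- counts_to_matrix(tpm)[, libs, drop = FALSE]
  rownames(m)[rowMeans(m) > threshold]
}

#' Per-gene footprint length histograms
#'
#' Tallies footprint read lengths per gene.  Input is either a pre-tabulated
#' per-gene length-count table (gene_id plus one column per read length,
#' summed over replicates before calling, in which case it is range-checked
#' and passed through), a tibble of alignment records, or a path to a BAM
#' file (read via Rsamtools).  Alignment records need columns `replicon`,
#' `strand`, `start` (1-based leftmost aligned base) and `length`; a read is
#' assigned to a gene when its alignment start lies within the gene interval
#' on the matching strand.  When the start falls in two overlapping genes
#' the read goes to the gene whose 5' end is nearer, ties broken by
#' annotation order.  Read lengths outside `lengths` are counted in an
#' overflow total and reported with a warning.
#'
#' @param x Length-count tibble, alignment tibble, or BAM path.
#' @param annotation Annotation tibble (`gene_id`, `replicon`, `strand`,
#'   `start`, `end`, `biotype`).
#' @param lengths Footprint length range to tally.
#' @return A list with `genes` (tibble: gene_id, one column per length,
#'   `total`), `all_cds` (one pooled histogram row summing counts over all
#'   coding genes before percentage conversion) and `overflow` (number of
#'   reads outside the length range).
#' @export
footprint_length_histogram <- function(x, annotation,
                                       lengths = ribote_default_lengths()) {
  if (is.character(x) && length(x) == 1) x <- read_bam_alignments(x)
  if (all(c("replicon", "strand", "start", "length") %in% names(x))) {
    tab <- assign_reads(x, annotation, lengths)
    overflow <- attr(tab, "overflow")
  } else if ("gene_id" %in% names(x)) {
    have <- setdiff(names(x), "gene_id")
    keep <- intersect(as.character(lengths), have)
    extra <- setdiff(have, as.character(lengths))
    overflow <- if (length(extra)) {
      sum(as.matrix(x[extra]))
    } else 0
    m <- matrix(0, nrow(x), length(lengths),
                dimnames = list(x$gene_id, as.character(lengths)))
    m[, keep] <- as.matrix(x[keep])
    tab <- matrix_to_counts(m)
  } else {
    abort("x must be a length table, alignment records, or a BAM path")
  }
  if (overflow > 0) {
    warn(sprintf("%d reads outside the %d-%d nt range were set aside",
                 overflow, min(lengths), max(lengths)))
  }
  m <- counts_to_matrix(tab)
  genes <- tab %>% mutate(total = unname(rowSums(m)))
  coding <- annotation$gene_id[annotation$biotype == "coding"]
  pooled <- colSums(m[rownames(m) %in% coding, , drop = FALSE])
  all_cds <- bind_cols(tibble(gene_id = "all_cds"),
                       as_tibble(as.list(pooled))) %>%
    mutate(total = sum(pooled))
  list(genes = genes, all_cds = all_cds, overflow = overflow)
}

assign_reads <- function(reads, annotation, lengths) {
  ann <- annotation %>% mutate(.ann_order = row_number())
  hits <- reads %>%
    mutate(.read = row_number()) %>%
    inner_join(ann, by = dplyr::join_by("replicon", "strand",
                                        between("start", "start", "end")),
               suffix = c("", ".gene")) %>%
    mutate(dist5 = if_else(.data$strand == "+",
                           .data$start - .data$start.gene,
                           .data$end - .data$start)) %>%
    group_by(.data$.read) %>%
    arrange(.data$dist5, .data$.ann_order, .by_group = TRUE) %>%
    dplyr::slice(1) %>%
    ungroup()
  in_range <- hits$length %in% lengths
  overflow <- sum(!in_range)
  hits <- hits[in_range, ]
  m <- matrix(0, nrow(annotation), length(lengths),
              dimnames = list(annotation$gene_id, as.character(lengths)))
  if (nrow(hits) > 0) {
    tt <- table(factor(hits$gene_id, levels = annotation$gene_id),
                factor(hits$length, levels = lengths))
    m[] <- as.numeric(tt)
  }
  out <- matrix_to_counts(m)
  attr(out, "overflow") <- overflow
  out
}

read_bam_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("reading BAM files requires Rsamtools")
  }
  b <- Rsamtools::scanBam(path, param = Rsamtools::ScanBamParam(
    what = c("rname", "strand", "pos", "qwidth"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)))[[1]]
  tibble(
    replicon = as.character(b$rname),
    strand = as.character(b$strand),
    start = b$pos,
    length = b$qwidth
  )
}

#' Livak (2^-ddCt) qPCR fold change
#'
#' \eqn{\Delta\Delta C_t = (C_{t,target}^{treated} - C_{t,ref}^{treated}) -
#' (C_{t,target}^{control} - C_{t,ref}^{control})}; the fold change is
#' \eqn{2^{-\Delta\Delta C_t}}.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Threshold-cycle values (finite reals; vectors are recycled).
#' @return Fold change(s).
#' @export
#' @examples
#' livak_fold_change(20, 18, 24, 18) # ddCt = -4 -> 16
livak_fold_change <- function(ct_target_treated, ct_ref_treated,
                              ct_target_control, ct_ref_control) {
  vals <- c(ct_target_treated, ct_ref_treated,
            ct_target_control, ct_ref_control)
  if (any(!is.finite(vals))) abort("Ct values must be finite")
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
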