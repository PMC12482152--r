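#' Pipeline configuration
#'
#' Collects every threshold the analysis applies, each defaulting to its
#' conventional value: 10 TPM detection cutoff, adjusted-p 0.05 and
#' |log2FC| 1 significance cutoffs, 65-read minimum for footprint-profile
#' classification, 30-nt minimum ORF length, and 0.01 high-confidence
#' cutoff on target-interaction p-values.  A YAML file with these keys may
#' be supplied instead.
#'
#' @param path Optional YAML file; keys override the defaults.
#' @param tpm_min,alpha,lfc_min,min_reads,orf_min_len,target_p_max
#'   Thresholds (all strict comparisons downstream).
#' @param seed Root seed for synthetic runs.
#' @param conditions Ordered condition labels (reference first).
#' @return A named list of class `ribote_config`.
#' @export
pipeline_config <- function(path = NULL, tpm_min = 10, alpha = 0.05,
                            lfc_min = 1, min_reads = 65, orf_min_len = 30,
                            target_p_max = 0.01, seed = 1L,
                            conditions = c("control", "stress")) {
  cfg <- list(tpm_min = tpm_min, alpha = alpha, lfc_min = lfc_min,
              min_reads = min_reads, orf_min_len = orf_min_len,
              target_p_max = target_p_max, seed = as.integer(seed),
              conditions = conditions)
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("reading a config file requires the yaml package")
    }
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  num <- c("tpm_min", "alpha", "lfc_min", "min_reads", "orf_min_len",
           "target_p_max")
  if (any(unlist(cfg[num]) <= 0)) abort("thresholds must be positive")
  structure(cfg, class = "ribote_config")
}

#' Validate pipeline inputs
#'
#' Cross-checks count matrices, metadata and annotation before any
#' computation: id agreement between counts and annotation, metadata/library
#' agreement, legal strand values, and (when sequences are provided)
#' intervals lying within their replicon.  Mismatched gene universes are
#' fatal; anything else is a warning.
#'
#' @param counts_rna,counts_ribo Count tibbles.
#' @param meta_rna,meta_ribo Library metadata tibbles.
#' @param annotation Annotation tibble.
#' @param genome Optional named character vector of replicon sequences.
#' @return A tibble of diagnostics (`severity`, `message`); zero rows means
#'   clean input.
#' @export
validate_inputs <- function(counts_rna, counts_ribo, meta_rna, meta_ribo,
                            annotation, genome = NULL) {
  diag <- list()
  note <- function(severity, message) {
    diag[[length(diag) + 1L]] <<- tibble(severity = severity,
                                         message = message)
  }
  for (nm in c("rna", "ribo")) {
    counts <- if (nm == "rna") counts_rna else counts_ribo
    meta <- if (nm == "rna") meta_rna else meta_ribo
    extra <- setdiff(counts$gene_id, annotation$gene_id)
    if (length(extra) > 0) {
      note("fatal", sprintf("%s counts contain %d gene(s) absent from the annotation (e.g. %s)",
                            nm, length(extra), extra[1]))
    }
    libs <- setdiff(names(counts), "gene_id")
    if (!setequal(libs, meta$library)) {
      note("fatal", sprintf("%s metadata does not match count libraries", nm))
    }
  }
  if (!all(annotation$strand %in% c("+", "-"))) {
    note("fatal", "annotation strand must be '+' or '-'")
  }
  if (!is.null(genome)) {
    lens <- nchar(genome)[annotation$replicon]
    bad <- is.na(lens) | annotation$end > lens | annotation$start < 1
    if (any(bad)) {
      note("fatal", sprintf("%d annotation interval(s) extend beyond their replicon",
                            sum(bad)))
    }
  }
  if (length(diag) == 0) {
    return(tibble(severity = character(), message = character()))
  }
  bind_rows(diag)
}

#' Run the full analysis end-to-end
#'
#' Executes quantification (TPM + detection), differential testing (RNA,
#' Ribo, TE), regulatory-class partition, per-condition footprint-profile
#' classification of sRNAs, smORF scanning of sRNA sequences, and
#' target-overlap statistics.  With `data = NULL` a complete synthetic
#' study is simulated from `config$seed` (including a synthetic
#' target-prediction table), so the pipeline runs self-contained.  Identical
#' config and seed give identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param data Optional named list with elements `counts` (list
#'   `rnaseq`/`riboseq`), `design`, `annotation` (as from
#'   [generate_annotation()]), `lengths_by_condition`, `classes`, and
#'   optionally `predictions` — the shape returned by [simulate_study()].
#' @param outdir Optional directory; every stage's table is written there
#'   as TSV.
#' @return A `ribote_report` list with all stage outputs and a `summary`
#'   tibble of headline counts.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL,
                         outdir = NULL) {
  if (is.null(data)) {
    data <- simulate_study(seed = config$seed)
    data$predictions <- simulate_predictions(data, config$seed)
  }
  design <- data$design
  conditions <- config$conditions
  meta_rna <- filter(as_tibble(design), .data$assay == "rnaseq")
  meta_ribo <- filter(as_tibble(design), .data$assay == "riboseq")
  diagnostics <- validate_inputs(data$counts$rnaseq, data$counts$riboseq,
                                 meta_rna, meta_ribo,
                                 data$annotation$annotation,
                                 data$annotation$genome)
  if (any(diagnostics$severity == "fatal")) {
    abort(paste0("input validation failed [stage=validate]: ",
                 paste(diagnostics$message, collapse = "; ")))
  }
  ann <- data$annotation$annotation
  # quantification
  tpm_rna <- compute_tpm(data$counts$rnaseq, ann)
  tpm_ribo <- compute_tpm(data$counts$riboseq, ann)
  detected <- list(
    rna = lapply(setNames(conditions, conditions), function(cond) {
      detection_filter(tpm_rna, meta_rna, cond, config$tpm_min)
    }),
    ribo = lapply(setNames(conditions, conditions), function(cond) {
      detection_filter(tpm_ribo, meta_ribo, cond, config$tpm_min)
    })
  )
  # differential testing
  res_rna <- nb_wald_test(data$counts$rnaseq, meta_rna, conditions)
  res_ribo <- nb_wald_test(data$counts$riboseq, meta_ribo, conditions)
  res_te <- te_interaction_test(data$counts$rnaseq, data$counts$riboseq,
                                meta_rna, meta_ribo, conditions)
  det_union <- list(rna = unique(unlist(detected$rna)),
                    ribo = unique(unlist(detected$ribo)))
  classes <- regulatory_class(res_rna, res_ribo, res_te,
                              alpha = config$alpha, lfc_min = config$lfc_min,
                              detected = unique(unlist(det_union)))
  # footprint-profile classification, per condition
  coding_calls <- purrr::imap(data$lengths_by_condition, function(hist, cond) {
    profiles <- build_profile_matrix(hist, data$classes,
                                     min_reads = config$min_reads)
    clustering <- cluster_profiles(profiles)
    classify_srnas(clustering, profiles, condition = cond)
  }) %>% bind_rows()
  # smORF scan over sRNA sequences
  srna_ids <- ann$gene_id[ann$biotype == "srna"]
  orfs <- purrr::map(srna_ids, function(id) {
    find_orfs(data$annotation$genes[[id]],
              min_len_nt = config$orf_min_len, parent_id = id)
  }) %>% bind_rows()
  # target overlap
  overlap <- if (!is.null(data$predictions)) {
    target_overlap(data$predictions, res_ribo, res_te,
                   p_max = config$target_p_max, alpha = config$alpha,
                   lfc_min = config$lfc_min, detected = det_union)
  }
  n_sig <- function(res, det) {
    nrow(significance_filter(res, config$alpha, config$lfc_min, det))
  }
  summary <- tibble(
    quantity = c("genes", "libraries",
                 paste0("detected_rna_", conditions),
                 paste0("detected_ribo_", conditions),
                 "sig_rna", "sig_ribo", "sig_te",
                 "srnas_coding_like", "srnas_insufficient_reads",
                 "smorf_candidates"),
    value = c(nrow(ann), nrow(design),
              vapply(detected$rna, length, 0L),
              vapply(detected$ribo, length, 0L),
              n_sig(res_rna, det_union$rna),
              n_sig(res_ribo, det_union$ribo),
              n_sig(res_te, unique(unlist(det_union))),
              sum(coding_calls$call == "coding_like"),
              sum(coding_calls$call == "insufficient_reads"),
              nrow(orfs))
  )
  report <- structure(list(
    config = config, diagnostics = diagnostics,
    tpm = list(rna = tpm_rna, ribo = tpm_ribo), detected = detected,
    results = list(rna = res_rna, ribo = res_ribo, te = res_te),
    regulatory_classes = classes, coding_calls = coding_calls,
    orfs = orfs, overlap = overlap, summary = summary
  ), class = "ribote_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

simulate_predictions <- function(data, seed, n_targets = 10) {
  ann <- data$annotation$annotation
  srnas <- ann$gene_id[ann$biotype == "srna"]
  coding <- ann$gene_id[ann$biotype == "coding"]
  with_stage_seed(seed, "predictions", {
    purrr::map(srnas, function(s) {
      tibble(srna_id = s,
             target_gene_id = sample(coding, min(n_targets, length(coding))),
             interaction_pvalue = runif(min(n_targets, length(coding)),
                                        0, 0.02))
    }) %>% bind_rows()
  })
}

write_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) {
    if (!is.null(x)) readr::write_tsv(x, file.path(outdir,
                                                   paste0(name, ".tsv")))
  }
  wr(report$tpm$rna, "tpm_rnaseq")
  wr(report$tpm$ribo, "tpm_riboseq")
  wr(report$results$rna, "differential_rnaseq")
  wr(report$results$ribo, "differential_riboseq")
  wr(report$results$te, "differential_te")
  wr(report$regulatory_classes, "regulatory_classes")
  wr(report$coding_calls, "srna_coding_calls")
  wr(report$orfs, "smorf_candidates")
  wr(report$overlap, "target_overlap")
  wr(report$summary, "summary")
  invisible(outdir)
}

#' @export
print.ribote_report <- function(x, ...) {
  cat("ribote pipeline report\n")
  cat("----------------------\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("%-28s %s\n", x$summary$quantity[i],
                format(x$summary$value[i])))
  }
  invisible(x)
}
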