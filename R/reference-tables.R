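#' Worked-example reference tables
#'
#' Loads the curated tables shipped with the package, transcribed from a
#' published oxidative-stress Ribo-seq/RNA-seq study of *Haloferax
#' volcanii*.  They serve as worked examples and fixtures for the filtering
#' and overlap statistics:
#'
#' * `srna_differential` — 17 sRNAs with differential ribosome occupancy or
#'   translational efficiency under oxidative stress: per-contrast log2 fold
#'   changes and adjusted p-values, TPMs, per-condition coding-cluster calls
#'   (Yes/No/NA), and protein-evidence flags.
#' * `srna_targets` — predicted mRNA targets of three stress-responsive
#'   sRNAs that were differentially translated (ribosome occupancy or TE),
#'   with the same statistics.
#' * `smorf_proteins` — seven small proteins encoded by sRNAs and detected
#'   by mass spectrometry (size, start/stop codon, whether the stop codon
#'   lies within the annotated sRNA region, TPMs).
#' * `tagged_srnas` — eight sRNA constructs assayed by Western blot, with
#'   the stop-codon-in-region flag from sequence-based ORF prediction.
#' * `target_predictions` — a *synthetic* stand-in for the full
#'   interaction-prediction table, which is not published in tabular form:
#'   the real differential targets plus clearly labelled
#'   `synth_target_*` filler rows so each sRNA reaches its published
#'   high-confidence target count (29 for sRNA_58, 42 for sRNA_77, 44 for
#'   sRNA_83).
#'
#' @return A named list of tibbles.
#' @export
#' @examples
#' tabs <- reference_tables()
#' nrow(tabs$srna_differential)
reference_tables <- function() {
  ext <- function(f) {
    readr::read_tsv(system.file("extdata", f, package = "ribote",
                                mustWork = TRUE),
                    show_col_types = FALSE, na = "NA", progress = FALSE)
  }
  list(
    srna_differential = ext("srna_differential.tsv"),
    srna_targets = ext("srna_targets.tsv"),
    smorf_proteins = ext("smorf_proteins.tsv"),
    tagged_srnas = ext("tagged_srnas.tsv"),
    target_predictions = ext("srna_target_predictions_synthetic.tsv")
  )
}

#' Extract one contrast from a wide reference results table
#'
#' The reference tables carry the RNA-seq, Ribo-seq and TE statistics side
#' by side; this pulls one contrast into the `gene_id`/`log2fc`/`padj`
#' layout that [significance_filter()] and [target_overlap()] expect.
#'
#' @param tab A wide table with `<contrast>_log2fc` / `<contrast>_padj`
#'   columns (e.g. from [reference_tables()]).
#' @param contrast `"rna"`, `"ribo"`, or `"te"`.
#' @param id_col Column holding the gene identifier.
#' @return A tibble with `gene_id`, `contrast`, `log2fc`, `padj`.
#' @export
reference_contrast <- function(tab, contrast = c("rna", "ribo", "te"),
                               id_col = intersect(
                                 c("gene_id", "target_gene_id"),
                                 names(tab))[1]) {
  contrast <- arg_match(contrast)
  lfc <- tab[[paste0(contrast, "_log2fc")]]
  padj <- tab[[paste0(contrast, "_padj")]]
  tibble(
    gene_id = tab[[id_col]],
    contrast = contrast,
    log2fc = lfc,
    padj = padj
  )
}
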