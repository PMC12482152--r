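#' Construct a table of synthetic gene specifications
#'
#' A gene specification row carries everything the simulator needs for one
#' gene: its biotype, length, negative-binomial (NB) expression parameters,
#' oxidative-stress effect sizes, footprint-length profile class, and an
#' optional embedded small ORF.  Counts are later drawn NB with mean
#' \eqn{\mu} and variance \eqn{\mu + \alpha \mu^2}, where `dispersion` is
#' \eqn{\alpha}; `dispersion = 0` degenerates to Poisson.  The stress effects
#' are additive on the log2 scale: RNA-seq stress libraries see
#' `txn_log2fc`, Ribo-seq stress libraries see `txn_log2fc + tln_log2fc`, so
#' `tln_log2fc` is the translation-only (TE) effect.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param biotype One of `"coding"`, `"structural_noncoding"`, `"srna"`
#'   (recycled).
#' @param length_nt Positive integer gene lengths; coding genes must be at
#'   least 30 nt.
#' @param baseline_mean Expected RNA-seq count in the control condition at
#'   size factor 1.
#' @param dispersion NB dispersion \eqn{\alpha} (variance
#'   \eqn{\mu + \alpha\mu^2}); non-negative.  Default 0.01, a 10%% biological
#'   coefficient of variation typical of tightly controlled microbial
#'   replicate cultures.
#' @param txn_log2fc Transcriptional stress effect (log2).
#' @param tln_log2fc Translation-only stress effect (log2), applied to
#'   Ribo-seq on top of `txn_log2fc`.
#' @param profile_class Footprint-length profile class: `"coding_peak"`,
#'   `"rrna_like"`, `"trna_like"`, or `"custom"`.
#' @param profile For `profile_class = "custom"`, a list of per-length
#'   probability vectors over `lengths` (each summing to 1).
#' @param has_smorf Logical; embed a sense-strand smORF in the gene sequence?
#' @param smorf_start_codon Start codon of the embedded smORF (one of
#'   ATG, GTG, TTG, CTG).
#' @param lengths Footprint length range the profiles are defined over.
#'
#' @return A tibble with one row per gene, class `ribote_gene_specs`.
#' @export
#' @examples
#' gene_specs(c("g1", "g2"), biotype = "coding", length_nt = 300,
#'            baseline_mean = c(100, 500))
gene_specs <- function(gene_id,
                       biotype = "coding",
                       length_nt = 600L,
                       baseline_mean = 200,
                       dispersion = 0.01,
                       txn_log2fc = 0,
                       tln_log2fc = 0,
                       profile_class = NULL,
                       profile = NULL,
                       has_smorf = FALSE,
                       smorf_start_codon = "ATG",
                       lengths = ribote_default_lengths()) {
  if (anyDuplicated(gene_id)) abort("duplicate gene ids in gene_specs()")
  n <- length(gene_id)
  biotype <- rep_len(biotype, n)
  bad <- setdiff(unique(biotype),
                 c("coding", "structural_noncoding", "srna"))
  if (length(bad) > 0) abort(paste("unknown biotype:", bad[1]))
  if (is.null(profile_class)) {
    profile_class <- if_else(biotype == "coding", "coding_peak", "rrna_like")
  }
  specs <- tibble(
    gene_id = as.character(gene_id),
    biotype = biotype,
    length_nt = as.integer(rep_len(length_nt, n)),
    baseline_mean = as.numeric(rep_len(baseline_mean, n)),
    dispersion = as.numeric(rep_len(dispersion, n)),
    txn_log2fc = as.numeric(rep_len(txn_log2fc, n)),
    tln_log2fc = as.numeric(rep_len(tln_log2fc, n)),
    profile_class = rep_len(profile_class, n),
    has_smorf = rep_len(has_smorf, n),
    smorf_start_codon = rep_len(smorf_start_codon, n)
  )
  if (any(specs$length_nt <= 0)) abort("gene lengths must be positive")
  if (any(specs$biotype == "coding" & specs$length_nt < 30)) {
    abort("coding genes must be at least 30 nt long")
  }
  if (any(specs$baseline_mean < 0) || any(specs$dispersion < 0)) {
    abort("baseline_mean and dispersion must be non-negative")
  }
  if (any(specs$has_smorf & !specs$smorf_start_codon %in% START_CODONS)) {
    abort("smorf_start_codon must be one of ATG, GTG, TTG, CTG")
  }
  if (any(specs$has_smorf & specs$length_nt < 33)) {
    abort("gene too short to embed a 30-nt smORF with flanking stop")
  }
  specs$profile <- build_profiles(specs$profile_class, profile, lengths)
  attr(specs, "lengths") <- lengths
  class(specs) <- c("ribote_gene_specs", class(specs))
  specs
}

# Per-length footprint probability vectors for the built-in profile classes.
# coding_peak mirrors elongating-ribosome footprints: >= 70% of mass on
# 24-27 nt with the mode at the characteristic 27 nt; rrna_like is a broad
# long-fragment distribution; trna_like a narrow peak near 31 nt.
profile_probs <- function(class, lengths = ribote_default_lengths()) {
  p <- switch(class,
    coding_peak = {
      v <- 0.002 + 0.02 * exp(-((lengths - 27)/4)^2)
      v[lengths == 24] <- 0.13
      v[lengths == 25] <- 0.15
      v[lengths == 26] <- 0.18
      v[lengths == 27] <- 0.28
      v
    },
    rrna_like = 0.01 + exp(-((lengths - 36)/5.5)^2),
    trna_like = 0.005 + exp(-((lengths - 31)/1.8)^2),
    abort(paste("unknown profile class:", class))
  )
  p / sum(p)
}

build_profiles <- function(classes, custom, lengths) {
  out <- vector("list", length(classes))
  ci <- 0L
  for (i in seq_along(classes)) {
    if (classes[i] == "custom") {
      ci <- ci + 1L
      if (is.null(custom) || length(custom) < ci) {
        abort("profile_class 'custom' requires a 'profile' vector per gene")
      }
      v <- custom[[ci]]
      if (length(v) != length(lengths)) {
        abort("custom profile length does not match the length range")
      }
      if (abs(sum(v) - 1) > 1e-9) abort("custom profile must sum to 1")
      out[[i]] <- v
    } else {
      out[[i]] <- profile_probs(classes[i], lengths)
    }
  }
  out
}

#' Describe the library layout of a two-condition, two-assay study
#'
#' @param n_replicates Biological replicates per condition per assay
#'   (default 4, the layout of a typical stress Ribo-seq study; at least 2
#'   are required for any differential test).
#' @param conditions Ordered pair of condition labels (control first).
#' @param assays Ordered pair of assay labels.
#' @param library_size_factors Optional positive per-library depth factors,
#'   recycled across the `2 * 2 * n_replicates` libraries in the row order of
#'   the returned tibble.  Default 1 for every library.
#' @param seed Integer root seed for all simulation stages.
#'
#' @return A tibble with columns `library`, `assay`, `condition`,
#'   `replicate`, `size_factor` and attribute `seed`.
#' @export
study_design <- function(n_replicates = 4,
                         conditions = c("control", "stress"),
                         assays = c("rnaseq", "riboseq"),
                         library_size_factors = NULL,
                         seed = 1L) {
  if (n_replicates < 2) abort("at least 2 replicates per condition required")
  if (length(conditions) != 2 || length(assays) != 2) {
    abort("exactly two conditions and two assays are required")
  }
  design <- tidyr::expand_grid(
    assay = assays, condition = conditions,
    replicate = seq_len(n_replicates)
  ) %>%
    mutate(library = paste(.data$assay, .data$condition, .data$replicate,
                           sep = "_"), .before = 1)
  sf <- if (is.null(library_size_factors)) 1 else library_size_factors
  design$size_factor <- rep_len(sf, nrow(design))
  if (any(design$size_factor <= 0)) abort("size factors must be positive")
  attr(design, "seed") <- as.integer(seed)
  attr(design, "conditions") <- conditions
  attr(design, "assays") <- assays
  class(design) <- c("ribote_design", class(design))
  design
}

#' Generate a synthetic annotation and matching sequences
#'
#' Genes are laid head-to-tail on a single synthetic replicon separated by
#' random spacers, each on a random strand.  Sequences are random at 60%% GC
#' (halophile-like).  Genes flagged `has_smorf` get an in-frame ORF with the
#' requested start codon and an in-region stop embedded on the sense strand;
#' genes not flagged are scrubbed so that no sense-strand ORF of at least
#' `orf_min_len` nt starting with any allowed start codon and terminated by
#' an in-frame stop remains.
#'
#' @param specs A [gene_specs()] tibble.
#' @param seed Integer seed; the same seed and specs give byte-identical
#'   output.
#' @param replicon Name of the synthetic replicon.
#' @param orf_min_len Minimum ORF length (nt, start through stop) used when
#'   scrubbing `has_smorf = FALSE` genes.
#'
#' @return A list with `annotation` (tibble: `gene_id`, `replicon`, `strand`,
#'   `start`, `end` 1-based inclusive, `biotype`, `length_nt`), `genes`
#'   (named character vector of sense-strand gene sequences) and `genome`
#'   (named character vector of replicon sequences).
#' @export
generate_annotation <- function(specs, seed = 1L, replicon = "repliconA",
                                orf_min_len = 30L) {
  if (anyDuplicated(specs$gene_id)) abort("duplicate gene ids")
  if (any(specs$length_nt <= 0)) abort("gene lengths must be positive")
  n <- nrow(specs)
  with_stage_seed(seed, "sequence", {
    gene_seq <- character(n)
    for (i in seq_len(n)) {
      s <- random_dna(specs$length_nt[i])
      if (isTRUE(specs$has_smorf[i])) {
        s <- embed_smorf(s, specs$smorf_start_codon[i], orf_min_len)
      } else {
        s <- scrub_orfs(s, orf_min_len)
      }
      gene_seq[i] <- s
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gaps <- sample(20:100, n, replace = TRUE)
    start <- integer(n)
    pos <- 1L
    for (i in seq_len(n)) {
      pos <- pos + gaps[i]
      start[i] <- pos
      pos <- pos + specs$length_nt[i]
    }
    tail_gap <- sample(20:100, 1)
    placed <- if_else(strand == "+", gene_seq, revcomp(gene_seq))
    genome <- paste0(
      paste0(vapply(seq_len(n), function(i) {
        paste0(random_dna(gaps[i]), placed[i])
      }, character(1)), collapse = ""),
      random_dna(tail_gap)
    )
    annotation <- tibble(
      gene_id = specs$gene_id,
      replicon = replicon,
      strand = strand,
      start = start,
      end = start + specs$length_nt - 1L,
      biotype = specs$biotype,
      length_nt = specs$length_nt
    )
    list(
      annotation = annotation,
      genes = setNames(gene_seq, specs$gene_id),
      genome = setNames(genome, replicon)
    )
  })
}

random_dna <- function(n, gc = 0.6) {
  if (n == 0) return("")
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc)/2, gc/2, gc/2, (1 - gc)/2)),
         collapse = "")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) {
           paste(rev(strsplit(s, "")[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

# Insert an ORF (start codon, stop-free body, stop codon) at a random offset.
embed_smorf <- function(seq, start_codon, min_len) {
  len <- nchar(seq)
  k_max <- len %/% 3L
  k_min <- max(ceiling(min_len / 3), 4L)
  k <- if (k_max > k_min) sample(k_min:min(k_max, 101L), 1) else k_min
  body <- safe_codons(k - 2L)
  orf <- paste0(start_codon, body, sample(STOP_CODONS, 1))
  off <- sample.int(len - 3L * k + 1L, 1) - 1L
  paste0(substr(seq, 1, off), orf, substr(seq, off + 3L * k + 1L, len))
}

# Sense codons that are neither stops nor alternative starts, so embedded
# ORF bodies neither truncate early nor spawn extra nested candidates.
safe_codons <- function(k) {
  if (k <= 0) return("")
  all3 <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                            c("A","C","G","T")), 1, paste0, collapse = "")
  ok <- setdiff(all3, c(STOP_CODONS, START_CODONS))
  paste0(sample(ok, k, replace = TRUE), collapse = "")
}

# Remove every qualifying sense-strand ORF by mutating its start codon's
# second base to C (no start or stop codon contains NCN at that offset, so
# the edit cannot create new starts or stops in that frame).
scrub_orfs <- function(seq, min_len) {
  for (iter in 1:25) {
    hits <- find_orfs(seq, min_len_nt = min_len, starts = START_CODONS)
    hits <- hits[!is.na(hits$stop_codon) & hits$stop_within_region, ]
    if (nrow(hits) == 0) return(seq)
    for (off in hits$start_offset) {
      substr(seq, off + 2L, off + 2L) <- "C"
    }
  }
  abort("failed to scrub ORFs from a non-smORF gene")
}

#' Simulate RNA-seq and Ribo-seq count matrices
#'
#' Counts are drawn independently per gene and library from a negative
#' binomial with mean \eqn{s_j \mu_g 2^{\delta}} where \eqn{\delta} collects
#' the condition/assay effects (`txn_log2fc` in stress for both assays,
#' plus `tln_log2fc` in stress for Ribo-seq) and variance
#' \eqn{\mu + \alpha_g \mu^2}; \eqn{\alpha_g = 0} gives Poisson draws.
#'
#' @param specs A [gene_specs()] tibble.
#' @param design A [study_design()] tibble (its `seed` attribute drives two
#'   independent per-assay streams).
#'
#' @return A list with tibbles `rnaseq` and `riboseq` (gene_id plus one
#'   column per library) and the `design`.
#' @export
simulate_counts <- function(specs, design) {
  if (any(specs$baseline_mean < 0)) abort("negative baseline mean")
  if (any(specs$dispersion < 0)) abort("negative dispersion")
  seed <- attr(design, "seed") %||% 1L
  conditions <- attr(design, "conditions") %||% unique(design$condition)
  stress <- conditions[2]
  draw_assay <- function(assay_name) {
    libs <- design[design$assay == assay_name, ]
    m <- matrix(0, nrow(specs), nrow(libs),
                dimnames = list(specs$gene_id, libs$library))
    for (j in seq_len(nrow(libs))) {
      lfc <- if (libs$condition[j] == stress) {
        specs$txn_log2fc +
          if (assay_name == (attr(design, "assays") %||%
                               unique(design$assay))[2]) {
            specs$tln_log2fc
          } else 0
      } else 0
      mu <- libs$size_factor[j] * specs$baseline_mean * 2^lfc
      pois <- specs$dispersion == 0
      y <- numeric(nrow(specs))
      if (any(pois)) y[pois] <- rpois(sum(pois), mu[pois])
      if (any(!pois)) {
        y[!pois] <- rnbinom(sum(!pois), mu = mu[!pois],
                            size = 1 / specs$dispersion[!pois])
      }
      m[, j] <- y
    }
    matrix_to_counts(m)
  }
  assays <- attr(design, "assays") %||% unique(design$assay)
  rnaseq <- with_stage_seed(seed, "counts_rnaseq", draw_assay(assays[1]))
  riboseq <- with_stage_seed(seed, "counts_riboseq", draw_assay(assays[2]))
  list(rnaseq = rnaseq, riboseq = riboseq, design = design)
}

#' Simulate per-gene footprint read-length tables
#'
#' Each gene's requested total is split across the configured length range
#' by a multinomial draw from the gene's profile-class probability vector.
#'
#' @param specs A [gene_specs()] tibble.
#' @param total_reads Named numeric vector (or single value recycled) of
#'   total footprint reads per gene; non-negative.
#' @param seed Integer seed.
#' @param lengths Footprint length range (columns of the output).
#'
#' @return A tibble with `gene_id` and one integer column per length; row
#'   sums equal the requested totals (all-zero rows are retained).
#' @export
simulate_footprint_lengths <- function(specs, total_reads, seed = 1L,
                                       lengths = attr(specs, "lengths") %||%
                                         ribote_default_lengths()) {
  totals <- if (is.null(names(total_reads))) {
    setNames(rep_len(total_reads, nrow(specs)), specs$gene_id)
  } else total_reads[specs$gene_id]
  totals[is.na(totals)] <- 0
  if (any(totals < 0)) abort("total_reads must be non-negative")
  with_stage_seed(seed, "lengths", {
    m <- matrix(0L, nrow(specs), length(lengths),
                dimnames = list(specs$gene_id, as.character(lengths)))
    for (i in seq_len(nrow(specs))) {
      p <- specs$profile[[i]]
      if (length(p) != length(lengths)) {
        abort("profile vector length does not match the length range")
      }
      if (totals[i] > 0) m[i, ] <- rmultinom(1, totals[i], p)[, 1]
    }
    matrix_to_counts(m)
  })
}

#' Simulate a complete two-condition Ribo-seq/RNA-seq study
#'
#' Convenience wrapper used by the pipeline, tests and examples: builds a
#' realistic mixed gene population (coding genes, rRNA/tRNA-like structural
#' genes, sRNAs), simulates annotation, counts and per-condition
#' footprint-length tables.  Footprint totals per condition are the summed
#' Ribo-seq counts across that condition's replicates.
#'
#' @param n_coding,n_rrna,n_trna,n_srna Population sizes.
#' @param prop_te_regulated Fraction of coding genes given a translation-only
#'   stress effect (half up, half down, |log2FC| = 2).
#' @param prop_coding_srna Fraction of sRNAs given a coding-like footprint
#'   profile and an embedded smORF.
#' @param dispersion NB dispersion for every gene.
#' @param seed Root seed.
#' @param n_replicates Replicates per condition per assay.
#'
#' @return A list: `specs`, `design`, `annotation` (with sequences),
#'   `counts` (list rnaseq/riboseq), `lengths_by_condition` (list of
#'   per-condition length tables), `classes` (gene_id/class tibble for the
#'   coding classifier).
#' @export
simulate_study <- function(n_coding = 60, n_rrna = 4, n_trna = 6,
                           n_srna = 20, prop_te_regulated = 0.2,
                           prop_coding_srna = 0.3, dispersion = 0.01,
                           seed = 1L, n_replicates = 4) {
  set.seed(stage_seed(seed, "annotation"))
  n_total <- n_coding + n_rrna + n_trna + n_srna
  ids <- c(sprintf("cds_%03d", seq_len(n_coding)),
           sprintf("rrna_%02d", seq_len(n_rrna)),
           sprintf("trna_%02d", seq_len(n_trna)),
           sprintf("srna_%03d", seq_len(n_srna)))
  biotype <- rep(c("coding", "structural_noncoding", "structural_noncoding",
                   "srna"), c(n_coding, n_rrna, n_trna, n_srna))
  profile_class <- rep(c("coding_peak", "rrna_like", "trna_like", "rrna_like"),
                       c(n_coding, n_rrna, n_trna, n_srna))
  n_cod_srna <- round(prop_coding_srna * n_srna)
  coding_srna <- seq_len(n_srna) <= n_cod_srna
  profile_class[n_coding + n_rrna + n_trna + which(coding_srna)] <-
    "coding_peak"
  length_nt <- c(pmax(90L, as.integer(round(rlnorm(n_coding, log(800), 0.5)))),
                 sample(1400:2900, n_rrna, replace = TRUE),
                 sample(72:90, n_trna, replace = TRUE),
                 sample(80:500, n_srna, replace = TRUE))
  baseline <- exp(runif(n_total, log(100), log(2000)))
  tln <- rep(0, n_total)
  n_te <- round(prop_te_regulated * n_coding)
  if (n_te > 0) {
    idx <- sample.int(n_coding, n_te)
    tln[idx] <- sample(c(-2, 2), n_te, replace = TRUE)
  }
  txn <- rep(0, n_total)
  txn[sample.int(n_total, round(0.1 * n_total))] <- sample(c(-1.5, 1.5),
    round(0.1 * n_total), replace = TRUE)
  specs <- gene_specs(
    gene_id = ids, biotype = biotype, length_nt = length_nt,
    baseline_mean = baseline, dispersion = dispersion,
    txn_log2fc = txn, tln_log2fc = tln, profile_class = profile_class,
    has_smorf = c(rep(FALSE, n_coding + n_rrna + n_trna), coding_srna),
    smorf_start_codon = "ATG"
  )
  design <- study_design(n_replicates = n_replicates, seed = seed)
  ann <- generate_annotation(specs, seed = seed)
  counts <- simulate_counts(specs, design)
  conditions <- attr(design, "conditions")
  ribo <- counts_to_matrix(counts$riboseq)
  lengths_by_condition <- lapply(seq_along(conditions), function(ci) {
    libs <- design$library[design$assay == attr(design, "assays")[2] &
                             design$condition == conditions[ci]]
    totals <- rowSums(ribo[, libs, drop = FALSE])
    simulate_footprint_lengths(specs, totals, seed = seed + ci)
  })
  names(lengths_by_condition) <- conditions
  classes <- tibble(
    gene_id = ids,
    class = rep(c("coding", "rrna", "trna", "srna"),
                c(n_coding, n_rrna, n_trna, n_srna))
  )
  list(specs = specs, design = design, annotation = ann, counts = counts,
       lengths_by_condition = lengths_by_condition, classes = classes)
}

#' Write annotation, sequences and sRNA intervals to standard formats
#'
#' Writes the replicon sequences as FASTA, the gene annotation as GFF3
#' (1-based inclusive coordinates, biotype in the attributes column) and the
#' sRNA intervals as BED (0-based half-open).  Output is deterministic:
#' identical inputs give byte-identical files.
#'
#' @param ann The list returned by [generate_annotation()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (fasta, gff3, bed).
#' @export
write_annotation <- function(ann, dir) {
  if (!requireNamespace("Biostrings", quietly = TRUE) ||
      !requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("writing annotation requires Biostrings and rtracklayer")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "genome.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(ann$genome), fasta)
  a <- ann$annotation
  gr <- GenomicRanges::GRanges(
    seqnames = a$replicon,
    ranges = IRanges::IRanges(start = a$start, end = a$end),
    strand = a$strand,
    source = "ribote", type = "gene",
    ID = a$gene_id, biotype = a$biotype
  )
  gff3 <- file.path(dir, "annotation.gff3")
  rtracklayer::export(gr, gff3, format = "gff3")
  bed <- file.path(dir, "srna.bed")
  s <- a[a$biotype == "srna", ]
  srna_gr <- GenomicRanges::GRanges(
    seqnames = s$replicon,
    ranges = IRanges::IRanges(start = s$start, end = s$end),
    strand = s$strand, name = s$gene_id, score = 0L
  )
  rtracklayer::export(srna_gr, bed, format = "bed")
  invisible(c(fasta = fasta, gff3 = gff3, bed = bed))
}
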