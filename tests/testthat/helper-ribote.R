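# Shared fixtures and independent oracles for the test suite.

# wide count tibble from a genes x libraries matrix of values
make_counts <- function(m, genes = NULL, libs = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(libs)) libs <- paste0("lib", seq_len(ncol(m)))
  dimnames(m) <- list(genes, libs)
  dplyr::bind_cols(tibble::tibble(gene_id = genes), tibble::as_tibble(m))
}

make_meta <- function(libs, condition, assay = "rnaseq") {
  tibble::tibble(library = libs, assay = assay, condition = condition,
                 replicate = stats::ave(seq_along(libs), condition,
                                        FUN = seq_along))
}

# two-condition metadata with n replicates each, library names prefixed
two_cond_meta <- function(n = 4, prefix = "lib") {
  libs <- paste0(prefix, seq_len(2 * n))
  make_meta(libs, rep(c("control", "stress"), each = n))
}

unit_size_factors <- function(libs) {
  tibble::tibble(library = libs, size_factor = 1)
}

poisson_dispersions <- function(genes) {
  tibble::tibble(gene_id = genes, dispersion = 1e-8)
}

# independent step-up implementation of Benjamini-Hochberg, straight from
# the definition: padj_(i) = min_{j >= i} min(1, m * p_(j) / j)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[i] <- min(pmin(1, m * ranked[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# two-sided Fisher exact p by hypergeometric summation of all tables with
# the observed margins whose probability does not exceed the observed one
fisher_oracle <- function(k, n_minus_k, K_minus_k, rest) {
  row1 <- k + n_minus_k
  col1 <- k + K_minus_k
  N <- k + n_minus_k + K_minus_k + rest
  support <- max(0, col1 - (N - row1)):min(row1, col1)
  probs <- stats::dhyper(support, row1, N - row1, col1)
  p_obs <- stats::dhyper(k, row1, N - row1, col1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force ORF enumeration: every (frame, start, first-stop) triple on
# the sense strand, length counted start through stop inclusive
orf_oracle <- function(seq, min_len = 30,
                       starts = c("ATG", "GTG", "TTG", "CTG")) {
  n <- nchar(seq)
  out <- list()
  for (frame in 0:2) {
    pos <- seq(frame + 1L, n - 2L, by = 3L)
    if (length(pos) == 0) next
    codons <- substring(seq, pos, pos + 2L)
    for (i in seq_along(codons)) {
      if (!codons[i] %in% starts) next
      j <- i
      found <- FALSE
      while (j <= length(codons)) {
        if (codons[j] %in% c("TAA", "TAG", "TGA")) {
          found <- TRUE
          break
        }
        j <- j + 1L
      }
      if (found && j > i) {
        len <- (j - i + 1L) * 3L
        if (len >= min_len) {
          out[[length(out) + 1L]] <- data.frame(
            frame = frame, start_offset = pos[i] - 1L,
            end_offset = pos[j] + 2L, start_codon = codons[i],
            stop_codon = codons[j], length_nt = len)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(frame = integer(), start_offset = integer(),
                      end_offset = integer(), start_codon = character(),
                      stop_codon = character(), length_nt = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start_offset, res$end_offset), , drop = FALSE]
}

random_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# histogram tibble with planted per-length counts over the default range
make_histogram <- function(gene_ids, counts_by_length,
                           lengths = 15:45) {
  m <- matrix(0, length(gene_ids), length(lengths),
              dimnames = list(gene_ids, as.character(lengths)))
  for (i in seq_along(counts_by_length)) {
    cl <- counts_by_length[[i]]
    m[i, as.character(as.integer(names(cl)))] <- unname(cl)
  }
  make_counts(m, genes = gene_ids, libs = as.character(lengths))
}

# multinomial profile draws for classifier tests
draw_profiles <- function(ids, class, totals, seed) {
  specs <- gene_specs(ids, biotype = "srna", length_nt = 200,
                      profile_class = class)
  simulate_footprint_lengths(specs, stats::setNames(totals, ids),
                             seed = seed)
}
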