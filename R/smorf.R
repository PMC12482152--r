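#' Scan a sequence for candidate small ORFs
#'
#' Scans the sense strand (optionally both strands) of a nucleotide sequence
#' for open reading frames that begin with one of the allowed start codons
#' and extend to the first in-frame stop.  Alternative initiation codons
#' (GTG, TTG, CTG) are allowed by default because archaeal smORFs are known
#' to initiate at them.  When no in-frame stop occurs inside the scanned
#' region and flanking `downstream` sequence is supplied, the scan continues
#' into the flank and the candidate is flagged `stop_within_region = FALSE`
#' — mirroring the situation where a predicted ORF's stop codon lies outside
#' the annotated sRNA interval.  Candidates without any stop (even in the
#' flank) are reported with `stop_codon = NA` when their readable span
#' reaches `min_len_nt`.
#'
#' ORF length is counted from the first base of the start codon through the
#' last base of the stop codon inclusive; nested starts sharing a stop are
#' all reported.
#'
#' @param sequence A single DNA string over A/C/G/T.
#' @param min_len_nt Minimum ORF length in nt, start through stop inclusive
#'   (default 30, i.e. proteins of at least 9 aa).
#' @param starts Allowed start codons.
#' @param downstream Optional flanking sequence appended for stop-codon
#'   search only (starts are only sought inside `sequence`).
#' @param both_strands Also scan the reverse complement?
#' @param parent_id Identifier copied into the output.
#'
#' @return A tibble with columns `parent_id`, `strand`, `frame` (0-2,
#'   relative to the scanned strand), `start_offset`/`end_offset` (0-based
#'   half-open on the scanned strand; `end_offset` can exceed the region
#'   length when the stop lies in the flank), `start_codon`, `stop_codon`
#'   (NA when absent), `length_nt`, `protein_length_aa`,
#'   `stop_within_region`.
#' @export
#' @examples
#' find_orfs("ATGAAATAG", min_len_nt = 0)
find_orfs <- function(sequence, min_len_nt = 30, starts = START_CODONS,
                      downstream = NULL, both_strands = FALSE,
                      parent_id = NA_character_) {
  check_dna(sequence)
  if (!is.null(downstream)) check_dna(downstream)
  if (min_len_nt < 3) min_len_nt <- 3
  out <- scan_strand(sequence, downstream, min_len_nt, starts, "+")
  if (both_strands) {
    out <- bind_rows(out,
      scan_strand(revcomp(sequence), NULL, min_len_nt, starts, "-"))
  }
  out$parent_id <- parent_id
  out[order(out$start_offset, out$end_offset), ] %>%
    select("parent_id", dplyr::everything())
}

check_dna <- function(x) {
  if (length(x) != 1 || !is.character(x)) abort("sequence must be one string")
  if (grepl("[^ACGT]", x)) abort("sequence contains characters outside ACGT")
  invisible(x)
}

scan_strand <- function(region, downstream, min_len, starts, strand) {
  full <- paste0(region, downstream %||% "")
  n_region <- nchar(region)
  n_full <- nchar(full)
  res <- list()
  for (frame in 0:2) {
    pos <- seq(frame + 1L, n_full - 2L, by = 3L)
    if (length(pos) == 0 || pos[1] > n_region - 2L) next
    codons <- substring(full, pos, pos + 2L)
    in_region <- pos + 2L <= n_region
    start_idx <- which(codons %in% starts & in_region)
    stop_idx <- which(codons %in% STOP_CODONS)
    for (si in start_idx) {
      nxt <- stop_idx[stop_idx > si]
      if (length(nxt) > 0) {
        ei <- nxt[1]
        len <- (ei - si + 1L) * 3L
        if (len < min_len) next
        res[[length(res) + 1L]] <- tibble(
          strand = strand, frame = frame,
          start_offset = pos[si] - 1L,
          end_offset = pos[ei] + 2L,
          start_codon = codons[si],
          stop_codon = codons[ei],
          length_nt = len,
          protein_length_aa = len %/% 3L - 1L,
          stop_within_region = pos[ei] + 2L <= n_region
        )
      } else {
        # open-ended candidate: readable span to the last full codon
        last <- length(codons)
        len <- (last - si + 1L) * 3L
        if (len < min_len) next
        res[[length(res) + 1L]] <- tibble(
          strand = strand, frame = frame,
          start_offset = pos[si] - 1L,
          end_offset = pos[last] + 2L,
          start_codon = codons[si],
          stop_codon = NA_character_,
          length_nt = len,
          protein_length_aa = len %/% 3L,
          stop_within_region = FALSE
        )
      }
    }
  }
  if (length(res) == 0) {
    return(tibble(
      strand = character(), frame = integer(), start_offset = integer(),
      end_offset = integer(), start_codon = character(),
      stop_codon = character(), length_nt = integer(),
      protein_length_aa = integer(), stop_within_region = logical()
    ))
  }
  bind_rows(res)
}

#' Check each reading frame of a region for an in-frame stop codon
#'
#' A frame is `TRUE` iff an in-frame stop codon lies wholly inside the
#' region; frames are numbered 0-2 relative to the region's first base.
#' An all-`FALSE` verdict reproduces the situation where a sequence-based
#' ORF predictor calls an ORF in an sRNA even though no stop codon is
#' contained in the predicted sRNA region.
#'
#' @param sequence DNA string containing the region.
#' @param region Length-2 integer vector, 1-based inclusive bounds of the
#'   region within `sequence` (default: the whole sequence).
#' @return Named logical vector of length 3 (`frame0`, `frame1`, `frame2`).
#' @export
stop_codon_check <- function(sequence, region = c(1L, nchar(sequence))) {
  check_dna(sequence)
  if (region[1] < 1 || region[2] > nchar(sequence) || region[1] > region[2]) {
    abort("region must lie within the sequence")
  }
  sub <- substr(sequence, region[1], region[2])
  n <- nchar(sub)
  out <- setNames(logical(3), paste0("frame", 0:2))
  for (frame in 0:2) {
    if (n - frame < 3) next
    pos <- seq(frame + 1L, n - 2L, by = 3L)
    out[frame + 1L] <- any(substring(sub, pos, pos + 2L) %in% STOP_CODONS)
  }
  out
}
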