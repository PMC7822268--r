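## Core domain types and elementary sequence operations.
##
## The internal alphabet is DNA: {A, C, G, T, N}. RNA input (U) is normalized
## to T on load; RNA is rendered only at output (see to_rna()). Coordinates
## are 0-based half-open internally and 1-based inclusive in user-facing CSV.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

## validate a DNA-alphabet string; errors name the first offending position
check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    of_stop(sprintf("%s must be a single character string", what), "invalid_sequence")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    of_stop(sprintf("invalid character '%s' in %s at position %d",
                    substr(seq, bad, bad), what, bad),
            "invalid_sequence")
  invisible(seq)
}

## normalize raw sequence text: uppercase, U -> T
normalize_dna <- function(seq) chartr("U", "T", toupper(seq))

#' Construct a transcript
#'
#' A transcript is an identified nucleotide sequence with gene and species
#' labels and an optional exon structure given as junction offsets.
#'
#' @param transcript_id Transcript identifier (non-empty string).
#' @param sequence Nucleotide sequence over `A,C,G,T,N` (lowercase and `U`
#'   are normalized on construction).
#' @param gene_id Gene identifier; defaults to `transcript_id`.
#' @param species Species label, e.g. `"human"`; default `"unknown"`.
#' @param exon_ends Ascending 0-based transcript offsets where an exon ends
#'   (exon-junction positions); empty for a single-exon transcript. Each
#'   junction `e` must satisfy `0 < e < nchar(sequence)`.
#' @param is_primary Whether this is the primary (design target) transcript.
#' @return An object of class `transcript`.
#' @examples
#' tx <- transcript("T1", "ACGUacgu", gene_id = "G1", species = "human")
#' tx$sequence  # "ACGTACGT"
#' @export
transcript <- function(transcript_id, sequence, gene_id = transcript_id,
                       species = "unknown", exon_ends = integer(),
                       is_primary = FALSE) {
  if (!is.character(transcript_id) || length(transcript_id) != 1L ||
      is.na(transcript_id) || !nzchar(transcript_id))
    of_stop("transcript_id must be a non-empty string", "invalid_transcript")
  sequence <- normalize_dna(sequence)
  check_dna(sequence, sprintf("sequence of '%s'", transcript_id))
  exon_ends <- as.integer(exon_ends)
  L <- nchar(sequence)
  if (length(exon_ends)) {
    if (any(exon_ends <= 0L) || any(exon_ends >= L))
      of_stop(sprintf("exon junction offsets of '%s' must lie strictly inside (0, %d)",
                      transcript_id, L), "invalid_transcript")
    if (is.unsorted(exon_ends, strictly = TRUE))
      of_stop(sprintf("exon junction offsets of '%s' must be strictly increasing",
                      transcript_id), "invalid_transcript")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 species = species, sequence = sequence,
                 exon_ends = exon_ends, is_primary = isTRUE(is_primary)),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript> %s | %s | %s | %d nt | %d junction(s)%s\n",
              x$transcript_id, x$gene_id, x$species, nchar(x$sequence),
              length(x$exon_ends), if (x$is_primary) " | primary" else ""))
  invisible(x)
}

#' Construct a SNP record
#'
#' @param transcript_id Transcript the SNP lies on.
#' @param pos 1-based transcript coordinate.
#' @param snp_id SNP identifier (e.g. an rs number).
#' @param ref_allele Reference allele (single base).
#' @param alt_alleles Character vector of alternate alleles.
#' @return A one-row data frame with an `alt_alleles` list column.
#' @export
snp_record <- function(transcript_id, pos, snp_id, ref_allele, alt_alleles) {
  data.frame(transcript_id = transcript_id, pos = as.integer(pos),
             snp_id = snp_id, ref_allele = ref_allele,
             alt_alleles = I(list(as.character(alt_alleles))))
}

#' Reverse complement of a DNA sequence
#'
#' `N` complements to `N`. The operation is an involution: applying it twice
#' returns the input.
#'
#' @param seq DNA string over `A,C,G,T,N`.
#' @return The reverse complement (same alphabet).
#' @examples
#' reverse_complement("ACGT")  # "ACGT" (palindromic)
#' reverse_complement("ACGN")  # "NCGT"
#' @export
reverse_complement <- function(seq) {
  check_dna(seq)
  if (!nchar(seq)) return(seq)
  intToUtf8(rev(utf8ToInt(chartr("ACGT", "TGCA", seq))))
}

#' Render a DNA sequence as RNA
#'
#' T becomes U; everything else is unchanged. Used only when presenting
#' siRNA strands; all internal computation stays in the DNA alphabet.
#'
#' @param seq DNA string.
#' @return RNA string.
#' @export
to_rna <- function(seq) {
  check_dna(seq)
  chartr("T", "U", seq)
}

#' GC content of a sequence
#'
#' Percentage of G and C bases. `N` counts in the denominator but never as
#' G or C (conservative policy for ambiguous bases).
#'
#' @param seq Non-empty DNA string.
#' @return Percentage in `[0, 100]`.
#' @export
gc_content <- function(seq) {
  check_dna(seq)
  n <- nchar(seq)
  if (n == 0L) of_stop("gc_content of an empty sequence is undefined", "empty_input")
  100 * (n - nchar(gsub("[GC]", "", seq, fixed = FALSE))) / n
}

#' Hamming distance between two equal-length sequences
#'
#' Positionwise mismatch count. Any comparison involving `N` counts as a
#' mismatch (including `N` vs `N`), so `hamming(a, a) == 0` only when `a`
#' is free of ambiguity codes.
#'
#' @param a,b DNA strings of equal length.
#' @return Integer mismatch count.
#' @export
hamming <- function(a, b) {
  check_dna(a); check_dna(b)
  if (nchar(a) != nchar(b))
    of_stop(sprintf("sequence lengths differ (%d vs %d)", nchar(a), nchar(b)),
            "length_mismatch")
  if (!nchar(a)) return(0L)
  ia <- utf8ToInt(a); ib <- utf8ToInt(b)
  n_code <- utf8ToInt("N")
  sum(ia != ib | ia == n_code | ib == n_code)
}
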