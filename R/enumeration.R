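## Candidate enumeration: every k-mer window tiling the primary transcript
## becomes one design candidate (ASO or siRNA duplex).

#' Enumerate all candidate oligos of length k against a transcript
#'
#' Produces one candidate per start offset `0 .. L - k`, in ascending start
#' order: exactly `L - k + 1` candidates for a transcript of length `L`.
#' The sense sequence is the transcript window (the siRNA passenger /
#' "parent sense"); the antisense sequence is its reverse complement (the
#' ASO, or the siRNA guide). Windows containing `N` are kept but flagged
#' with `has_ambiguity` so the selection stage can drop them.
#'
#' @param primary A [transcript] (the design target).
#' @param k Oligo length in nt (`>= 8`); conventionally 20 for ASOs and 19
#'   for siRNAs.
#' @param design_type `"ASO"` or `"SIRNA"`.
#' @param add_tt_overhang siRNA only: append a dTdT 3' overhang when
#'   rendering strands (see [sirna_strands()]). Overhang bases never enter
#'   search or annotation windows.
#' @return A data frame of class `oligo_candidates` with columns
#'   `oligo_id`, `design_type`, `start`, `end` (0-based half-open),
#'   `sense_seq`, `antisense_seq`, `has_ambiguity`. Attributes carry the
#'   primary transcript/gene IDs, `k` and the overhang flag.
#' @export
enumerate_candidates <- function(primary, k, design_type = c("ASO", "SIRNA"),
                                 add_tt_overhang = FALSE) {
  design_type <- match.arg(design_type)
  stopifnot(inherits(primary, "transcript"))
  k <- as.integer(k)
  if (k < 8L) of_stop("k must be >= 8", "config")
  L <- nchar(primary$sequence)
  if (L < k)
    of_stop(sprintf("transcript '%s' (L = %d) is shorter than k = %d: nothing to enumerate",
                    primary$transcript_id, L, k), "empty_enumeration")
  starts <- 0:(L - k)
  sense <- substring(primary$sequence, starts + 1L, starts + k)
  antisense <- vapply(sense, reverse_complement, character(1), USE.NAMES = FALSE)
  out <- data.frame(
    oligo_id = sprintf("%s_%d", primary$transcript_id, starts + 1L),
    design_type = design_type,
    start = starts,
    end = starts + k,
    sense_seq = sense,
    antisense_seq = antisense,
    has_ambiguity = grepl("N", sense, fixed = TRUE),
    stringsAsFactors = FALSE
  )
  structure(out,
            class = c("oligo_candidates", "data.frame"),
            primary_id = primary$transcript_id,
            primary_gene_id = primary$gene_id,
            k = k, add_tt_overhang = isTRUE(add_tt_overhang))
}

## subsetting keeps the candidate-table attributes
#' @export
`[.oligo_candidates` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "primary_id") <- attr(x, "primary_id")
    attr(out, "primary_gene_id") <- attr(x, "primary_gene_id")
    attr(out, "k") <- attr(x, "k")
    attr(out, "add_tt_overhang") <- attr(x, "add_tt_overhang")
    class(out) <- class(x)
  }
  out
}

#' Render siRNA guide and passenger strands
#'
#' The guide (antisense) and passenger (sense) strands are rendered in RNA.
#' With `add_tt_overhang`, a dTdT overhang is appended to the 3' end of both
#' strands; it is shown lowercase (`"tt"`, DNA) and is excluded from every
#' search and annotation window.
#'
#' @param candidates An siRNA candidate table (or subset).
#' @param add_tt_overhang Overrides the enumeration-time flag when not `NULL`.
#' @return Data frame with columns `oligo_id`, `guide`, `passenger`.
#' @export
sirna_strands <- function(candidates, add_tt_overhang = NULL) {
  if (!all(candidates$design_type == "SIRNA"))
    of_stop("sirna_strands applies to SIRNA candidates only", "design_type")
  overhang <- add_tt_overhang %||% isTRUE(attr(candidates, "add_tt_overhang"))
  guide <- vapply(candidates$antisense_seq, to_rna, character(1), USE.NAMES = FALSE)
  passenger <- vapply(candidates$sense_seq, to_rna, character(1), USE.NAMES = FALSE)
  if (overhang) {
    guide <- paste0(guide, "tt")
    passenger <- paste0(passenger, "tt")
  }
  data.frame(oligo_id = candidates$oligo_id, guide = guide,
             passenger = passenger, stringsAsFactors = FALSE)
}
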