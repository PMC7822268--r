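## Per-candidate annotation: GC content, SNP overlap, exon-junction
## spanning, and conservation against splice variants / orthologs.

#' Annotate GC content
#'
#' Adds `gc_percent`: the GC percentage of the sense window (N counts in
#' the denominator only).
#'
#' @param candidates Candidate table.
#' @return The table with a `gc_percent` column.
#' @export
annotate_gc <- function(candidates) {
  n <- nchar(candidates$sense_seq)
  gc <- n - nchar(gsub("[GC]", "", candidates$sense_seq))
  candidates$gc_percent <- 100 * gc / n
  candidates
}

#' Annotate SNP overlap
#'
#' A SNP overlaps a candidate when its 1-based position lies within the
#' candidate's window (`start_1based <= pos <= end_1based`). Adds
#' `snp_count` and `snp_ids` (IDs joined with `;` in ascending position
#' order). SNPs on other transcripts are ignored.
#'
#' @param candidates Candidate table.
#' @param snps SNP data frame from [read_snps()].
#' @return The table with `snp_count` and `snp_ids` columns.
#' @export
annotate_snps <- function(candidates, snps) {
  primary_id <- attr(candidates, "primary_id")
  snps <- snps[snps$transcript_id == primary_id, , drop = FALSE]
  snps <- snps[order(snps$pos), , drop = FALSE]
  count <- integer(nrow(candidates))
  ids <- character(nrow(candidates))
  if (nrow(snps)) {
    for (i in seq_len(nrow(candidates))) {
      inside <- snps$pos >= candidates$start[i] + 1L & snps$pos <= candidates$end[i]
      count[i] <- sum(inside)
      ids[i] <- paste(snps$snp_id[inside], collapse = ";")
    }
  }
  candidates$snp_count <- count
  candidates$snp_ids <- ids
  candidates
}

#' Annotate exon-junction spanning
#'
#' A candidate spans a junction when a junction offset lies strictly inside
#' its window (`start < e < end`, 0-based half-open): an oligo merely
#' abutting a junction does not cross it. Adds the `spans_junction` flag
#' and `junction_count`.
#'
#' @param candidates Candidate table.
#' @param primary The primary [transcript] (its `exon_ends` are used; a
#'   single-exon transcript yields all-FALSE/0).
#' @return The table with `spans_junction` and `junction_count` columns.
#' @export
annotate_junction <- function(candidates, primary) {
  ends <- primary$exon_ends
  if (length(ends) == 0L) {
    candidates$spans_junction <- FALSE
    candidates$junction_count <- 0L
    return(candidates)
  }
  count <- vapply(seq_len(nrow(candidates)), function(i)
    sum(ends > candidates$start[i] & ends < candidates$end[i]), integer(1))
  candidates$spans_junction <- count > 0L
  candidates$junction_count <- count
  candidates
}

#' Annotate conservation against other transcripts
#'
#' For each non-primary transcript (splice variant or ortholog), computes
#' the minimum Hamming distance of the sense window over all windows of
#' that transcript, capped at `max_mm`; values beyond the cap are reported
#' as `NA` ("absent"). Adds one `mm_<transcript_id>` column per transcript,
#' and one `conserved_<species>` flag per species, true when some
#' transcript of that species matches with 0 mismatches.
#'
#' @param candidates Candidate table.
#' @param others Named list of [transcript] objects to compare against.
#' @param max_mm Mismatch cap (default 2).
#' @return The annotated table.
#' @export
annotate_conservation <- function(candidates, others, max_mm = 2L) {
  species_hit <- list()
  for (tx in others) {
    idx <- build_index(list(tx), db_name = tx$transcript_id)
    hits <- search_index(idx, candidates$sense_seq, max_mm)
    mm <- rep(NA_integer_, nrow(candidates))
    if (nrow(hits)) {
      best <- tapply(hits$mismatches, hits$query_idx, min)
      mm[as.integer(names(best))] <- as.integer(best)
    }
    candidates[[paste0("mm_", tx$transcript_id)]] <- mm
    sp <- tx$species
    hit0 <- !is.na(mm) & mm == 0L
    species_hit[[sp]] <- if (is.null(species_hit[[sp]])) hit0 else species_hit[[sp]] | hit0
  }
  for (sp in names(species_hit))
    candidates[[paste0("conserved_", sp)]] <- species_hit[[sp]]
  candidates
}
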