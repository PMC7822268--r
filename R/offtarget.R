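## Off-target search and gene-level counting.
##
## The search replaces an external short-read aligner with an internal
## pigeonhole engine: the query is split into 3 segments; any occurrence
## with <= 2 mismatches must match one segment exactly, so exact lookup of
## the segments followed by full Hamming verification finds every hit.
## Databases are stored as given (sense text); callers supply the query
## that is expected to occur verbatim in the text for the strand of
## interest, so there is a single canonical search direction.

#' Build a seed index over a sequence database
#'
#' @param transcripts Named list of [transcript] objects (the database).
#' @param db_name Label for the database, e.g. `"cdna"` or `"gene"`.
#' @param seg_count Number of pigeonhole segments; 3 guarantees completeness
#'   at up to 2 mismatches.
#' @return A `seed_index` object.
#' @export
build_index <- function(transcripts, db_name = "cdna", seg_count = 3L) {
  if (length(transcripts) == 0L)
    of_stop(sprintf("cannot build index '%s' from an empty database", db_name),
            "empty_database")
  structure(list(
    db_name = db_name,
    seg_count = as.integer(seg_count),
    transcript_ids = vapply(transcripts, `[[`, character(1), "transcript_id"),
    gene_ids = vapply(transcripts, `[[`, character(1), "gene_id"),
    sequences = vapply(transcripts, `[[`, character(1), "sequence")
  ), class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat(sprintf("<seed_index> '%s': %d sequence(s), %d pigeonhole segments\n",
              x$db_name, length(x$sequences), x$seg_count))
  invisible(x)
}

#' Search queries against a seed index
#'
#' Reports every occurrence of each query in any database sequence with
#' Hamming distance up to `max_mm`, exactly once, on the forward strand of
#' the stored text. `N` in query or text always counts as a mismatch.
#'
#' @param index A `seed_index` from [build_index()].
#' @param queries Character vector of DNA queries (each of length at least
#'   `3 * seg_count`; queries of mixed lengths are batched internally).
#' @param max_mm Maximum mismatches (0-2).
#' @return Data frame with one row per hit: `query_idx`, `query`,
#'   `transcript_id`, `gene_id`, `offset` (0-based), `mismatches`.
#' @export
search_index <- function(index, queries, max_mm = 2L) {
  stopifnot(inherits(index, "seed_index"))
  max_mm <- as.integer(max_mm)
  if (max_mm < 0L || max_mm > index$seg_count - 1L)
    of_stop(sprintf("max_mm must be between 0 and %d for %d segments",
                    index$seg_count - 1L, index$seg_count), "config")
  lens <- nchar(queries)
  if (any(lens < 3L * index$seg_count))
    of_stop(sprintf("query too short: minimum length is %d for %d pigeonhole segments",
                    3L * index$seg_count, index$seg_count), "query_too_short")
  pieces <- lapply(unique(lens), function(k) {
    sel <- which(lens == k)
    hits <- cpp_pigeonhole_search(queries[sel], unname(index$sequences),
                                  max_mm, index$seg_count)
    hits$query_idx <- sel[hits$query_idx]
    hits
  })
  hits <- do.call(rbind, pieces)
  hits <- hits[order(hits$query_idx, hits$text_idx, hits$offset), , drop = FALSE]
  data.frame(query_idx = hits$query_idx,
             query = queries[hits$query_idx],
             transcript_id = unname(index$transcript_ids[hits$text_idx]),
             gene_id = unname(index$gene_ids[hits$text_idx]),
             offset = hits$offset,
             mismatches = hits$mismatches,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Summarize hits into distinct-gene off-target counts
#'
#' Each gene is counted once, at the minimum mismatch level over all of its
#' hits; the intended target gene never contributes.
#'
#' @param hits Hit table from [search_index()] (one query, or pre-filtered).
#' @param target_gene_id Gene ID of the intended target, excluded from all
#'   counts.
#' @return Named integer vector `c(genes_mm0, genes_mm1, genes_mm2)`.
#' @export
summarize_hits <- function(hits, target_gene_id) {
  out <- c(genes_mm0 = 0L, genes_mm1 = 0L, genes_mm2 = 0L)
  if (is.null(hits) || nrow(hits) == 0L) return(out)
  hits <- hits[hits$gene_id != target_gene_id, , drop = FALSE]
  if (nrow(hits) == 0L) return(out)
  min_mm <- tapply(hits$mismatches, hits$gene_id, min)
  tab <- tabulate(min_mm + 1L, nbins = 3L)
  c(genes_mm0 = tab[1], genes_mm1 = tab[2], genes_mm2 = tab[3])
}

## batch: per-query gene-level summaries -> n x 3 integer matrix
summarize_hits_batch <- function(hits, target_gene_id, n_queries) {
  out <- matrix(0L, nrow = n_queries, ncol = 3L,
                dimnames = list(NULL, c("genes_mm0", "genes_mm1", "genes_mm2")))
  if (nrow(hits) == 0L) return(out)
  hits <- hits[hits$gene_id != target_gene_id, , drop = FALSE]
  if (nrow(hits) == 0L) return(out)
  key <- paste(hits$query_idx, hits$gene_id, sep = "\r")
  min_mm <- tapply(hits$mismatches, key, min)
  qi <- as.integer(sub("\r.*$", "", names(min_mm)))
  for (lvl in 0:2) {
    cnt <- table(qi[min_mm == lvl])
    if (length(cnt)) out[as.integer(names(cnt)), lvl + 1L] <- as.integer(cnt)
  }
  out
}

#' Add off-target properties to candidates
#'
#' For siRNA, only the cDNA database is searched, for both strands: the
#' guide strand pairs the transcript text, so its target-matching query is
#' the sense sequence (stored as `cdna_mm0/1/2`); the passenger's
#' target-matching query is the antisense sequence (`cdna_pass_mm0/1/2`).
#' For ASO design the sense sequence is searched against both the cDNA and
#' the unspliced-gene databases (`cdna_mm0/1/2`, `gene_mm0/1/2`). Counts are
#' distinct genes at their minimum mismatch level, excluding the target
#' gene.
#'
#' @param candidates Candidate table from [enumerate_candidates()].
#' @param cdna_index Seed index over the cDNA (transcript) database.
#' @param gene_index Seed index over unspliced gene sequences; required for
#'   ASO design.
#' @param max_mm Maximum mismatches (default 2).
#' @param target_gene_id Gene excluded from counts; defaults to the
#'   candidates' primary gene.
#' @return The candidate table with off-target count columns added.
#' @export
offtarget_profile <- function(candidates, cdna_index, gene_index = NULL,
                              max_mm = 2L,
                              target_gene_id = attr(candidates, "primary_gene_id")) {
  stopifnot(inherits(cdna_index, "seed_index"))
  n <- nrow(candidates)
  profile_one <- function(index, queries) {
    hits <- search_index(index, queries, max_mm)
    summarize_hits_batch(hits, target_gene_id, n)
  }
  if (all(candidates$design_type == "SIRNA")) {
    guide <- profile_one(cdna_index, candidates$sense_seq)
    pass <- profile_one(cdna_index, candidates$antisense_seq)
    candidates$cdna_mm0 <- guide[, 1]; candidates$cdna_mm1 <- guide[, 2]
    candidates$cdna_mm2 <- guide[, 3]
    candidates$cdna_pass_mm0 <- pass[, 1]; candidates$cdna_pass_mm1 <- pass[, 2]
    candidates$cdna_pass_mm2 <- pass[, 3]
  } else {
    if (is.null(gene_index))
      of_stop("ASO off-target profiling requires an unspliced-gene index", "config")
    cdna <- profile_one(cdna_index, candidates$sense_seq)
    gene <- profile_one(gene_index, candidates$sense_seq)
    candidates$cdna_mm0 <- cdna[, 1]; candidates$cdna_mm1 <- cdna[, 2]
    candidates$cdna_mm2 <- cdna[, 3]
    candidates$gene_mm0 <- gene[, 1]; candidates$gene_mm1 <- gene[, 2]
    candidates$gene_mm2 <- gene[, 3]
  }
  candidates
}
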