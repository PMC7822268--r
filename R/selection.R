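## The selection funnel: hard filters (SNPs, non-specific motifs, perfect
## off-target matches, conservation, score) followed by a positional-
## diversity final pick.

#' Selection funnel configuration
#'
#' @param filter_snps Reject candidates overlapping any known SNP.
#' @param motif_filters List of `motif_rule`s (or patterns) rejecting
#'   candidates whose antisense sequence matches; defaults to poly-G and
#'   poly-T runs of 4+.
#' @param max_perfect_offtargets Maximum allowed distinct genes with a
#'   perfect (0-mismatch) cDNA off-target match; 0 rejects any perfect hit,
#'   `NULL` disables the filter.
#' @param require_conserved_species Species whose `conserved_<species>`
#'   flag must be TRUE.
#' @param min_score Optional list `list(property =, min =)`: reject when
#'   the named score property falls below `min`.
#' @param n_select Number of candidates in the final pick.
#' @param diversity_pick Use the positional-diversity pick (otherwise the
#'   first `n_select` survivors are taken).
#' @return A `selection_config` object.
#' @export
selection_config <- function(filter_snps = TRUE,
                             motif_filters = list(run_rule("G", 4L), run_rule("T", 4L)),
                             max_perfect_offtargets = 0L,
                             require_conserved_species = character(),
                             min_score = NULL,
                             n_select = 10L,
                             diversity_pick = TRUE) {
  motif_filters <- lapply(motif_filters, function(m) {
    if (inherits(m, "motif_rule")) m else motif_rule(as.character(m), 1.0)
  })
  n_select <- as.integer(n_select)
  if (n_select < 1L) of_stop("n_select must be >= 1", "config")
  if (!is.null(max_perfect_offtargets)) {   # NULL disables the off-target filter
    max_perfect_offtargets <- as.integer(max_perfect_offtargets)
    if (max_perfect_offtargets < 0L)
      of_stop("max_perfect_offtargets must be >= 0", "config")
  }
  if (!is.null(min_score) && is.null(min_score$property))
    of_stop("min_score must name a score property", "config")
  structure(list(filter_snps = isTRUE(filter_snps),
                 motif_filters = motif_filters,
                 max_perfect_offtargets = max_perfect_offtargets,
                 require_conserved_species = as.character(require_conserved_species),
                 min_score = min_score,
                 n_select = n_select,
                 diversity_pick = isTRUE(diversity_pick)),
            class = "selection_config")
}

need_property <- function(candidates, prop, filter) {
  if (is.null(candidates[[prop]]))
    of_stop(sprintf("the '%s' filter is enabled but property '%s' is missing",
                    filter, prop), "config")
  candidates[[prop]]
}

#' Apply the hard filters of the selection funnel
#'
#' A candidate is rejected with all applicable reason labels, evaluated in
#' the fixed order `snp`, `motif`, `offtarget`, `conservation`, `score`;
#' survivors keep their input order. Filtering is idempotent: re-filtering
#' the survivors rejects nothing.
#'
#' @param candidates Annotated candidate table.
#' @param cfg A [selection_config()].
#' @return List with `selected` (surviving oligo IDs, input order) and
#'   `rejected` (named list: oligo ID -> character vector of reasons).
#' @export
apply_filters <- function(candidates, cfg = selection_config()) {
  n <- nrow(candidates)
  reasons <- vector("list", n)
  add <- function(reasons, hit, label) {
    hit[is.na(hit)] <- FALSE
    for (i in which(hit)) reasons[[i]] <- c(reasons[[i]], label)
    reasons
  }
  if (cfg$filter_snps)
    reasons <- add(reasons, need_property(candidates, "snp_count", "snp") > 0L, "snp")
  if (length(cfg$motif_filters)) {
    hit <- rep(FALSE, n)
    for (rule in cfg$motif_filters)
      hit <- hit | grepl(rule$pattern, candidates$antisense_seq)
    reasons <- add(reasons, hit, "motif")
  }
  if (!is.null(cfg$max_perfect_offtargets))
    reasons <- add(reasons,
                   need_property(candidates, "cdna_mm0", "offtarget") >
                     cfg$max_perfect_offtargets,
                   "offtarget")
  for (sp in cfg$require_conserved_species)
    reasons <- add(reasons,
                   !need_property(candidates, paste0("conserved_", sp),
                                  "conservation"),
                   "conservation")
  if (!is.null(cfg$min_score))
    reasons <- add(reasons,
                   need_property(candidates, cfg$min_score$property, "score") <
                     cfg$min_score$min,
                   "score")
  rejected_idx <- which(lengths(reasons) > 0L)
  list(selected = candidates$oligo_id[setdiff(seq_len(n), rejected_idx)],
       rejected = stats::setNames(reasons[rejected_idx],
                                  candidates$oligo_id[rejected_idx]))
}

#' Positional-diversity pick
#'
#' Greedy max-min spread over start positions: seed with the smallest
#' start, then repeatedly add the survivor maximizing the minimum distance
#' to the already-picked starts (ties broken by smaller start). A greedy
#' max-min pick is a 2-approximation of the optimal spread. The result is
#' returned sorted by start.
#'
#' @param survivors Candidate table subset (the funnel survivors).
#' @param n_select Number of candidates wanted.
#' @return Character vector of `min(n_select, nrow(survivors))` oligo IDs,
#'   ordered by start position (empty, with a log line, when no survivor).
#' @export
diversity_pick <- function(survivors, n_select) {
  if (nrow(survivors) == 0L) {
    of_log("diversity_pick", n_survivors = 0, n_selected = 0)
    return(character())
  }
  starts <- survivors$start
  ord <- order(starts)
  starts <- starts[ord]
  ids <- survivors$oligo_id[ord]
  n_take <- min(as.integer(n_select), length(starts))
  picked <- 1L                       # smallest start seeds the pick
  while (length(picked) < n_take) {
    mind <- vapply(seq_along(starts), function(i)
      min(abs(starts[i] - starts[picked])), numeric(1))
    mind[picked] <- -1
    picked <- c(picked, which.max(mind))  # which.max: first index wins ties
  }
  picked <- sort(picked)
  ids[picked]
}

#' Run the full selection funnel
#'
#' [apply_filters()] then the final pick ([diversity_pick()] or the first
#' `n_select` survivors). Also annotates the candidate table with the CSV
#' columns `selected` (0/1) and `reject_reasons`.
#'
#' @param candidates Annotated candidate table.
#' @param cfg A [selection_config()].
#' @return List of class `selection_result`: `selected` (final oligo IDs),
#'   `survivors` (all filter survivors), `rejected` (reason map), and
#'   `candidates` (the annotated table).
#' @export
select_oligos <- function(candidates, cfg = selection_config()) {
  funnel <- apply_filters(candidates, cfg)
  surv <- candidates[candidates$oligo_id %in% funnel$selected, , drop = FALSE]
  final <- if (cfg$diversity_pick) diversity_pick(surv, cfg$n_select)
           else utils::head(surv$oligo_id, cfg$n_select)
  candidates$selected <- as.integer(candidates$oligo_id %in% final)
  candidates$reject_reasons <- vapply(candidates$oligo_id, function(id) {
    r <- funnel$rejected[[id]]
    if (is.null(r)) "" else paste(r, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  of_log("select", n_in = nrow(candidates), n_survivors = nrow(surv),
         n_selected = length(final))
  structure(list(selected = final, survivors = funnel$selected,
                 rejected = funnel$rejected, candidates = candidates),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d candidate(s): %d survived filters, %d selected\n",
              nrow(x$candidates), length(x$survivors), length(x$selected)))
  invisible(x)
}
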