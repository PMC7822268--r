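## Efficacy and liability scoring.
##
## siRNA: a fixed point-based checklist in the style of the Reynolds
## design rules (presence/absence of key duplex features adds or removes
## points). The scorer sits behind a pluggable interface (config key
## `efficacy_scorer`) so a trained model can replace it. ASO: a composite
## of target affinity (nearest-neighbor dG), penalized sequence motifs
## associated with toxicity or promiscuity, and self-structure liabilities.

#' Create a motif rule
#'
#' @param pattern Regular expression over the DNA alphabet, or use
#'   [run_rule()] for homopolymer runs.
#' @param penalty Non-negative penalty in score points.
#' @param label Human-readable label.
#' @return A `motif_rule` object.
#' @export
motif_rule <- function(pattern, penalty, label = pattern) {
  if (penalty < 0) of_stop("motif penalty must be >= 0", "config")
  structure(list(pattern = pattern, penalty = penalty, label = label),
            class = "motif_rule")
}

#' Homopolymer-run motif rule
#'
#' @param base Single base (`A`, `C`, `G` or `T`).
#' @param n Minimum run length.
#' @param penalty Penalty points.
#' @return A `motif_rule` matching runs of `n` or more consecutive `base`.
#' @export
run_rule <- function(base, n, penalty = 1.0) {
  motif_rule(sprintf("%s{%d,}", base, n), penalty,
             label = sprintf("poly%s(%d)", base, n))
}

#' Default ASO motif penalty table
#'
#' Poly-G runs (toxicity / non-specific binding) carry a full point;
#' poly-A, poly-T and poly-C runs half a point each.
#'
#' @return List of `motif_rule` objects.
#' @export
default_aso_motifs <- function() {
  list(run_rule("G", 4L, 1.0), run_rule("A", 4L, 0.5),
       run_rule("T", 4L, 0.5), run_rule("C", 4L, 0.5))
}

## the fixed 19-mer checklist, applied to the sense (passenger) strand
sirna_checklist <- function(sense) {
  b <- strsplit(sense, "")[[1]]
  gc <- gc_content(sense)
  pts <- 0L
  if (gc >= 30 && gc <= 52) pts <- pts + 1L                      # moderate GC
  pts <- pts + sum(b[15:19] %in% c("A", "T"))                    # 3' sense-end A/U richness
  if (hairpin_screen(sense, min_stem = 4L) == 0L) pts <- pts + 1L # no internal stem
  if (b[19] == "A") pts <- pts + 1L
  if (b[3] == "A") pts <- pts + 1L
  if (b[10] == "T") pts <- pts + 1L                              # U at cleavage site
  if (b[19] %in% c("G", "C")) pts <- pts - 1L
  if (b[13] == "G") pts <- pts - 1L
  max(pts, 0L)
}

#' Point-based siRNA efficacy score
#'
#' Scores each 19-mer siRNA duplex on its sense (passenger) strand with a
#' fixed checklist (positions 1-based 1..19): +1 for GC content in
#' 30-52%; +1 per A/T at positions 15-19; +1 when no hairpin stem of 4+ bp
#' exists; +1 for A at position 19; +1 for A at position 3; +1 for T (U)
#' at position 10; -1 for G/C at position 19; -1 for G at position 13;
#' floored at 0. The maximum is 10. Candidates with `k != 19` or ambiguous
#' bases are not applicable and score `NA`.
#'
#' @param candidates siRNA candidate table.
#' @return The table with an integer `sirna_score` column in `[0, 10]`.
#' @export
sirna_point_score <- function(candidates) {
  if (!all(candidates$design_type == "SIRNA"))
    of_stop("sirna_point_score applies to SIRNA candidates only", "design_type")
  score <- rep(NA_integer_, nrow(candidates))
  applicable <- nchar(candidates$sense_seq) == 19L & !candidates$has_ambiguity
  score[applicable] <- vapply(candidates$sense_seq[applicable],
                              sirna_checklist, integer(1), USE.NAMES = FALSE)
  candidates$sirna_score <- score
  candidates
}

#' ASO liability/affinity score
#'
#' `score = S_affinity - P_motif - P_self`, where `S_affinity` rescales
#' the oligo:target duplex stability (`-duplex_dg37`) linearly from
#' `a_min` to `a_max` kcal/mol and clamps to `[0, 1]` (weak binders score
#' 0); `P_motif` sums the penalties of motif rules matching the antisense
#' sequence; `P_self` adds 0.5 for a strong self-dimer
#' (`self_dimer_dg37 < self_dimer_cut`) and 0.5 for a long hairpin stem
#' (`hairpin_stem_max >= hairpin_cut`). Higher is better; with the default
#' penalty table the score lies in `[-2, 1]`.
#'
#' @param candidates ASO candidate table carrying the [thermo_profile()]
#'   columns.
#' @param motifs List of `motif_rule`s (default [default_aso_motifs()]).
#' @param a_min,a_max Affinity rescaling window, kcal/mol.
#' @param self_dimer_cut,hairpin_cut Self-structure thresholds.
#' @return The table with an `aso_score` column.
#' @export
aso_score <- function(candidates, motifs = default_aso_motifs(),
                      a_min = 10, a_max = 25,
                      self_dimer_cut = -8, hairpin_cut = 6L) {
  if (!all(candidates$design_type == "ASO"))
    of_stop("aso_score applies to ASO candidates only", "design_type")
  if (is.null(candidates$duplex_dg37))
    of_stop("aso_score requires thermo_profile() columns (duplex_dg37 missing)",
            "dependency")
  s_aff <- pmin(pmax((-candidates$duplex_dg37 - a_min) / (a_max - a_min), 0), 1)
  p_motif <- rep(0, nrow(candidates))
  for (rule in motifs)
    p_motif <- p_motif + rule$penalty * grepl(rule$pattern, candidates$antisense_seq)
  p_self <- 0.5 * (candidates$self_dimer_dg37 < self_dimer_cut) +
    0.5 * (candidates$hairpin_stem_max >= hairpin_cut)
  candidates$aso_score <- s_aff - p_motif - p_self
  candidates
}

#' Weighted composite score
#'
#' Linear combination `sum(weight * property)` over named numeric
#' properties; the all-purpose "mathematical formula" for ranking. A
#' missing or non-numeric property is an error, never a silent zero.
#'
#' @param candidates Candidate table.
#' @param weights Named numeric vector or list: property name -> weight
#'   (weights may be negative). An empty set yields 0 for all candidates.
#' @return The table with a `composite` column.
#' @export
composite_score <- function(candidates, weights) {
  weights <- unlist(weights)
  total <- rep(0, nrow(candidates))
  for (prop in names(weights)) {
    v <- candidates[[prop]]
    if (is.null(v))
      of_stop(sprintf("composite_score: property '%s' is missing", prop),
              "named_property")
    if (is.logical(v)) v <- as.numeric(v)
    if (!is.numeric(v))
      of_stop(sprintf("composite_score: property '%s' is not numeric", prop),
              "named_property")
    total <- total + weights[[prop]] * v
  }
  candidates$composite <- total
  candidates
}

#' Apply the configured efficacy scorer
#'
#' Dispatches on the `efficacy_scorer` config key: `"default"` runs the
#' built-in point-based checklist for siRNA (ASO candidates are scored by
#' [aso_score()] instead); any function is called as
#' `fn(candidates)` and must return the table with a score column, so a
#' trained model can be dropped in.
#'
#' @param candidates Candidate table.
#' @param scorer `"default"` or a function.
#' @return The scored candidate table.
#' @export
apply_efficacy_scorer <- function(candidates, scorer = "default") {
  if (is.function(scorer)) return(scorer(candidates))
  if (!identical(scorer, "default"))
    of_stop(sprintf("unknown efficacy_scorer '%s'", scorer), "config")
  if (all(candidates$design_type == "SIRNA")) sirna_point_score(candidates)
  else candidates
}
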