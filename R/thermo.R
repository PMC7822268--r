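## Nearest-neighbor duplex thermodynamics and simplified intra-/inter-
## molecular structure screens.
##
## Duplex stability is modeled as a sum of dinucleotide stack free energies
## plus initiation (and, for the DNA:DNA set, terminal) terms. Two
## parameter sets ship as plain-text TSVs under inst/extdata: a DNA:DNA
## unified set and a DNA:RNA hybrid set (for an unmodified DNA ASO bound to
## its RNA target), both keyed on the oligo strand 5'->3'. Structure
## screens are deliberately simple surrogates (best ungapped self-dimer,
## longest hairpin stem) rather than partition-function calculations.

GAS_CONSTANT <- 1.987     # cal/(mol K)
TEMP_37 <- 310.15         # K

.nn_cache <- new.env(parent = emptyenv())

#' Load a nearest-neighbor parameter set
#'
#' @param name `"dna_dna"` (unified DNA:DNA set), `"dna_rna"` (DNA:RNA
#'   hybrid set), or a path to a TSV with columns `dimer`, `dH`, `dS`,
#'   `dG37` and optional rows `init`, `init_term_AT`, `init_term_GC`.
#'   Units: kcal/mol (dH, dG37), cal/(mol K) (dS).
#' @return An `nn_params` object. Every loaded set is checked for internal
#'   consistency: `dG37` must equal `dH - 310.15 * dS / 1000` within
#'   0.05 kcal/mol for every entry.
#' @export
load_nn_params <- function(name = c("dna_dna", "dna_rna")) {
  if (length(name) == 1L && file.exists(name)) {
    path <- name
  } else {
    name <- match.arg(name)
    if (!is.null(.nn_cache[[name]])) return(.nn_cache[[name]])
    path <- system.file("extdata", paste0("nn_", name, ".tsv"),
                        package = "oligofunnel", mustWork = TRUE)
  }
  name <- name[1L]
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  bad <- abs(tab$dG37 - (tab$dH - TEMP_37 * tab$dS / 1000)) > 0.05
  if (any(bad))
    of_stop(sprintf("parameter set '%s': dG37 inconsistent with dH/dS for %s",
                    path, paste(tab$dimer[bad], collapse = ", ")),
            "bad_parameters")
  special <- c("init", "init_term_AT", "init_term_GC")
  stacks <- tab[!tab$dimer %in% special, , drop = FALSE]
  need <- as.vector(outer(c("A","C","G","T"), c("A","C","G","T"), paste0))
  if (!all(need %in% stacks$dimer))
    of_stop(sprintf("parameter set '%s' is missing stacks: %s", path,
                    paste(setdiff(need, stacks$dimer), collapse = ", ")),
            "bad_parameters")
  as_terms <- function(row) {
    if (nrow(row) == 0L) NULL
    else c(dH = row$dH, dS = row$dS, dG37 = row$dG37)
  }
  params <- structure(list(
    name = name,
    dH = stats::setNames(stacks$dH, stacks$dimer),
    dS = stats::setNames(stacks$dS, stacks$dimer),
    dG37 = stats::setNames(stacks$dG37, stacks$dimer),
    init = as_terms(tab[tab$dimer == "init", , drop = FALSE]),
    term_at = as_terms(tab[tab$dimer == "init_term_AT", , drop = FALSE]),
    term_gc = as_terms(tab[tab$dimer == "init_term_GC", , drop = FALSE])
  ), class = "nn_params")
  if (name %in% c("dna_dna", "dna_rna")) .nn_cache[[name]] <- params
  params
}

check_thermo_seq <- function(seq) {
  check_dna(seq)
  if (grepl("N", seq, fixed = TRUE))
    of_stop("thermodynamic calculation undefined for ambiguous base N", "ambiguity")
  if (nchar(seq) < 2L)
    of_stop("sequence too short for a nearest-neighbor sum (need >= 2 nt)",
            "too_short")
  invisible(seq)
}

## sum a component ("dH", "dS" or "dG37") over stacks + init + terminal terms
nn_sum <- function(seq, params, component) {
  n <- nchar(seq)
  dimers <- substring(seq, 1:(n - 1L), 2:n)
  total <- sum(params[[component]][dimers])
  if (!is.null(params$init)) total <- total + params$init[[component]]
  for (endbase in c(substr(seq, 1, 1), substr(seq, n, n))) {
    term <- if (endbase %in% c("A", "T")) params$term_at else params$term_gc
    if (!is.null(term)) total <- total + term[[component]]
  }
  total
}

#' Nearest-neighbor duplex free energy
#'
#' Standard free energy at 37 C (kcal/mol) of the duplex formed by `seq`
#' and its perfect Watson-Crick complement: initiation plus the sum of the
#' `nchar(seq) - 1` dinucleotide stacks plus terminal corrections (when the
#' parameter set defines them).
#'
#' @param seq DNA string over `A,C,G,T` (the oligo strand, 5'->3').
#' @param params An `nn_params` set from [load_nn_params()].
#' @return dG37 in kcal/mol (negative = stable).
#' @export
nn_duplex_dg <- function(seq, params = load_nn_params("dna_dna")) {
  check_thermo_seq(seq)
  nn_sum(seq, params, "dG37")
}

#' Two-state duplex melting temperature
#'
#' `Tm = 1000 * dH / (dS + R * ln(CT / 4)) - 273.15` with
#' `R = 1.987 cal/(mol K)`, plus the salt correction
#' `16.6 * log10(na_conc)` when `na_conc != 1`. Assumes a non-self-
#' complementary duplex at total strand concentration `oligo_conc`.
#'
#' @param seq DNA string (oligo strand).
#' @param params Parameter set.
#' @param oligo_conc Total strand concentration, molar (> 0).
#' @param na_conc Monovalent cation concentration, molar (> 0).
#' @return Melting temperature in degrees Celsius.
#' @export
nn_duplex_tm <- function(seq, params = load_nn_params("dna_dna"),
                         oligo_conc = 1e-6, na_conc = 1.0) {
  check_thermo_seq(seq)
  if (oligo_conc <= 0 || na_conc <= 0)
    of_stop("concentrations must be positive", "domain")
  dH <- nn_sum(seq, params, "dH")
  dS <- nn_sum(seq, params, "dS")
  tm <- dH * 1000 / (dS + GAS_CONSTANT * log(oligo_conc / 4)) - 273.15
  if (na_conc != 1.0) tm <- tm + 16.6 * log10(na_conc)
  tm
}

comp_base <- function(x) chartr("ACGT", "TGCA", x)

#' Best ungapped antiparallel self-dimer free energy
#'
#' Slides the sequence against a second copy of itself in antiparallel
#' orientation and scores every maximal run of two or more contiguous
#' complementary base pairs as the nearest-neighbor duplex energy of that
#' run's subsequence. Returns the most negative run energy, or 0 when no
#' run of length >= 2 exists (or none is stabilizing).
#'
#' @param seq DNA string over `A,C,G,T`.
#' @param params Parameter set (DNA:DNA by default: a self-dimer is an
#'   oligo:oligo duplex).
#' @return dG37 in kcal/mol, always `<= 0`.
#' @export
self_dimer_dg <- function(seq, params = load_nn_params("dna_dna")) {
  check_thermo_seq(seq)
  n <- nchar(seq)
  bases <- strsplit(seq, "")[[1]]
  best <- 0
  ## pair (i, j) is complementary when bases[i] == comp(bases[j]);
  ## antiparallel register: i + j constant
  for (o in 2:(2 * n)) {
    i_lo <- max(1L, o - n); i_hi <- min(n, o - 1L)
    if (i_hi < i_lo + 1L) next
    is <- i_lo:i_hi
    ok <- bases[is] == comp_base(bases[o - is])
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (ri in which(r$values & r$lengths >= 2L)) {
      run_seq <- substr(seq, is[starts[ri]], is[ends[ri]])
      dg <- nn_duplex_dg(run_seq, params)
      if (dg < best) best <- dg
    }
  }
  best
}

#' Longest hairpin stem
#'
#' Exhaustive scan for the longest contiguous inverted repeat (stem) whose
#' intervening loop has at least `min_loop` nt. Stems shorter than
#' `min_stem` report 0.
#'
#' @param seq DNA string over `A,C,G,T`.
#' @param min_stem Minimum reportable stem length (bp).
#' @param min_loop Minimum loop length (nt).
#' @return Maximum stem length in bp (0 when below `min_stem`).
#' @export
hairpin_screen <- function(seq, min_stem = 4L, min_loop = 3L) {
  check_dna(seq)
  n <- nchar(seq)
  best <- 0L
  max_len <- (n - min_loop) %/% 2L
  if (max_len < 1L) return(0L)
  for (len in max_len:1L) {
    if (len <= best) break
    for (i in 1:(n - 2L * len - min_loop + 1L)) {
      arm <- substr(seq, i, i + len - 1L)
      for (j in (i + len + min_loop):(n - len + 1L)) {
        if (arm == reverse_complement(substr(seq, j, j + len - 1L))) {
          best <- len
          break
        }
      }
      if (best == len) break
    }
  }
  if (best >= min_stem) best else 0L
}

#' Thermodynamic profile of candidates
#'
#' Computes, on the antisense (oligo) strand of each candidate:
#' `duplex_dg37` and `duplex_tm` against the RNA target (DNA:RNA hybrid
#' parameters by default), `self_dimer_dg37` and `hairpin_stem_max`
#' (oligo:oligo, DNA:DNA parameters). Candidates containing `N` get `NA`.
#'
#' @param candidates Candidate table.
#' @param duplex_params Parameter set for the oligo:target duplex.
#' @param self_params Parameter set for the self-dimer screen.
#' @param oligo_conc,na_conc Passed to [nn_duplex_tm()].
#' @return The table with the four thermodynamic columns added.
#' @export
thermo_profile <- function(candidates,
                           duplex_params = load_nn_params("dna_rna"),
                           self_params = load_nn_params("dna_dna"),
                           oligo_conc = 1e-6, na_conc = 1.0) {
  n <- nrow(candidates)
  dg <- tm <- sd <- rep(NA_real_, n)
  hp <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (candidates$has_ambiguity[i]) next
    a <- candidates$antisense_seq[i]
    dg[i] <- nn_duplex_dg(a, duplex_params)
    tm[i] <- nn_duplex_tm(a, duplex_params, oligo_conc, na_conc)
    sd[i] <- self_dimer_dg(a, self_params)
    hp[i] <- hairpin_screen(a)
  }
  candidates$duplex_dg37 <- dg
  candidates$duplex_tm <- tm
  candidates$self_dimer_dg37 <- sd
  candidates$hairpin_stem_max <- hp
  candidates
}
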