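## HELM-style monomer notation for chemically modified oligonucleotides,
## plus three text renderings (component/HELM string, sequence view, block
## view). The monomer registry is closed and small: 4 sugars, 6 bases, 2
## backbone linkers — enough for the chemistries a gapmer or siRNA design
## typically carries (DNA, RNA, LNA, 2'OMe; phosphodiester or
## phosphorothioate backbone; 5-methyl-C).

SUGARS <- c("dR", "R", "LR", "mR")           # DNA, RNA, LNA, 2'OMe
BASES <- c("A", "C", "G", "T", "U", "5mC")
LINKERS <- c("P", "sP")                       # phosphodiester, phosphorothioate

#' Construct a modified oligo
#'
#' An ordered 5'->3' list of monomers, each a (sugar, base, 3'-linker)
#' triple. Exactly the last monomer has no 3' linker.
#'
#' @param sugars Character vector over `dR` (DNA), `R` (RNA), `LR` (LNA),
#'   `mR` (2'OMe).
#' @param bases Character vector over `A,C,G,T,U,5mC`, same length.
#' @param linkers 3' linkers: length `n` with last element `"none"`, or
#'   length `n - 1`; values `P` or `sP`.
#' @param strand_id Strand identifier used in the HELM string.
#' @return A `modified_oligo` object.
#' @export
modified_oligo <- function(sugars, bases, linkers = "P", strand_id = "RNA1") {
  n <- length(sugars)
  if (n == 0L) of_stop("a modified oligo needs at least one monomer", "notation")
  if (length(bases) != n)
    of_stop("sugars and bases must have the same length", "notation")
  if (n == 1L && length(linkers) == 1L && linkers != "none") linkers <- "none"
  if (length(linkers) == 1L && n > 1L) linkers <- rep(linkers, n - 1L)
  if (length(linkers) == n - 1L) linkers <- c(linkers, "none")
  if (length(linkers) != n || linkers[n] != "none")
    of_stop("exactly the last monomer must have linker 'none'", "notation")
  bad <- setdiff(sugars, SUGARS)
  if (length(bad)) of_stop(sprintf("unknown sugar token '%s'", bad[1]), "unknown_monomer")
  bad <- setdiff(bases, BASES)
  if (length(bad)) of_stop(sprintf("unknown base token '%s'", bad[1]), "unknown_monomer")
  bad <- setdiff(linkers[-n], LINKERS)
  if (length(bad)) of_stop(sprintf("unknown linker token '%s'", bad[1]), "unknown_monomer")
  structure(list(strand_id = strand_id, sugars = unname(sugars),
                 bases = unname(bases), linkers = unname(linkers)),
            class = "modified_oligo")
}

#' Unmodified DNA oligo
#'
#' @param seq DNA sequence (`A,C,G,T`).
#' @param strand_id Strand identifier.
#' @return A `modified_oligo` with `dR` sugars and phosphodiester backbone.
#' @export
dna_oligo <- function(seq, strand_id = "RNA1") {
  check_dna(seq)
  b <- strsplit(seq, "")[[1]]
  modified_oligo(rep("dR", length(b)), b, strand_id = strand_id)
}

#' LNA gapmer from a DNA sequence
#'
#' The classic RNase H-recruiting design: a central DNA gap flanked by
#' locked-nucleic-acid wings, on a fully phosphorothioated backbone.
#'
#' @param seq DNA sequence of the full oligo.
#' @param wing Number of LNA monomers at each end (default 3).
#' @param backbone Backbone linker throughout (default `"sP"`).
#' @param strand_id Strand identifier.
#' @return A `modified_oligo`.
#' @export
gapmer <- function(seq, wing = 3L, backbone = "sP", strand_id = "RNA1") {
  check_dna(seq)
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  if (n < 2L * wing + 1L)
    of_stop(sprintf("sequence of %d nt cannot carry two %d-monomer wings", n, wing),
            "notation")
  sugars <- rep("dR", n)
  sugars[c(seq_len(wing), (n - wing + 1L):n)] <- "LR"
  modified_oligo(sugars, b, rep(backbone, n - 1L), strand_id = strand_id)
}

helm_token <- function(x) ifelse(nchar(x) > 1L, paste0("[", x, "]"), x)

#' Write a modified oligo as a HELM string
#'
#' Emits `<strand_id>{unit.unit...}$$$$` with
#' `unit = sugarToken(base)linkerToken`; single-character tokens are bare,
#' multi-character tokens bracketed (`[dR]`, `[LR]`, `[sP]`). One
#' canonical string per oligo.
#'
#' @param o A `modified_oligo`.
#' @return The HELM string.
#' @examples
#' helm_write(dna_oligo("ACG"))
#' @export
helm_write <- function(o) {
  stopifnot(inherits(o, "modified_oligo"))
  n <- length(o$sugars)
  link_tok <- c(helm_token(o$linkers[-n]), "")
  units <- paste0(helm_token(o$sugars), "(", o$bases, ")", link_tok)
  paste0(o$strand_id, "{", paste(units, collapse = "."), "}$$$$")
}

#' Parse a HELM string
#'
#' Inverse of [helm_write()] on its dialect. Unknown monomer tokens raise
#' an error naming the token; grammar violations raise a parse error with
#' the character offset of the offending unit.
#'
#' @param s A HELM string.
#' @return A `modified_oligo`.
#' @export
helm_parse <- function(s) {
  m <- regmatches(s, regexec("^([A-Za-z0-9]+)\\{(.*)\\}\\$\\$\\$\\$$", s))[[1]]
  if (length(m) != 3L)
    of_stop("HELM parse error at offset 1: expected '<id>{...}$$$$'", "parse")
  strand_id <- m[2]
  body <- m[3]
  units <- strsplit(body, ".", fixed = TRUE)[[1]]
  if (!length(units) || !nzchar(body))
    of_stop("HELM parse error: empty monomer list", "parse")
  unit_re <- "^(\\[[^]\\[]+\\]|[A-Za-z0-9])\\(([^()]+)\\)(\\[[^]\\[]+\\]|[A-Za-z0-9])?$"
  offset <- nchar(strand_id) + 2L   # 1-based offset of the first unit
  sugars <- bases <- character(length(units))
  linkers <- character(length(units))
  strip <- function(tok) sub("^\\[(.*)\\]$", "\\1", tok)
  for (i in seq_along(units)) {
    um <- regmatches(units[i], regexec(unit_re, units[i]))[[1]]
    if (length(um) == 0L)
      of_stop(sprintf("HELM parse error at offset %d: malformed unit '%s'",
                      offset, units[i]), "parse")
    sugars[i] <- strip(um[2])
    bases[i] <- strip(um[3])
    linkers[i] <- if (nzchar(um[4])) strip(um[4]) else "none"
    offset <- offset + nchar(units[i]) + 1L
  }
  if (any(linkers[-length(units)] == "none"))
    of_stop("HELM parse error: missing linker on an internal monomer", "parse")
  if (linkers[length(units)] != "none")
    of_stop("HELM parse error: trailing linker on the terminal monomer", "parse")
  modified_oligo(sugars, bases, linkers, strand_id = strand_id)
}

## per-monomer letter in the sequence view: case carries the sugar
seq_letter <- function(sugar, base) {
  letter <- if (base == "5mC") "C" else base   # 5mC displays as C
  switch(sugar,
         dR = tolower(letter),
         R = toupper(letter),
         LR = paste0("+", toupper(letter)),
         mR = paste0("m", toupper(letter)))
}

#' Sequence view of a modified oligo
#'
#' Standard compact notation: DNA lowercase, RNA uppercase, LNA `+X`,
#' 2'OMe `mX`; a phosphorothioate linkage is drawn as `*` between letters
#' (a text stand-in for graphical backbone marks). An unmodified DNA oligo
#' renders as its plain lowercase sequence.
#'
#' @param o A `modified_oligo`.
#' @return A single string.
#' @export
render_sequence <- function(o) {
  stopifnot(inherits(o, "modified_oligo"))
  n <- length(o$sugars)
  letters <- mapply(seq_letter, o$sugars, o$bases, USE.NAMES = FALSE)
  seps <- c(ifelse(o$linkers[-n] == "sP", "*", ""), "")
  paste0(paste0(letters, seps), collapse = "")
}

#' Block view of a modified oligo
#'
#' Three fixed-width lines emphasizing the modification pattern: line 1
#' carries one sugar-class token per monomer (`[d] [R] [L] [m]`), line 2
#' the base letters, line 3 the backbone marks (`*` under each
#' phosphorothioate linkage).
#'
#' @param o A `modified_oligo`.
#' @return A single string with three LF-separated lines.
#' @export
render_blocks <- function(o) {
  stopifnot(inherits(o, "modified_oligo"))
  n <- length(o$sugars)
  sugar_tok <- c(dR = "[d]", R = "[R]", LR = "[L]", mR = "[m]")[o$sugars]
  base_tok <- sprintf("%-3s", o$bases)
  link_tok <- c(ifelse(o$linkers[-n] == "sP", " * ", "   "), "   ")
  paste(paste(sugar_tok, collapse = " "),
        paste(base_tok, collapse = " "),
        paste(link_tok, collapse = " "),
        sep = "\n")
}

#' @export
print.modified_oligo <- function(x, ...) {
  cat(sprintf("<modified_oligo> %s (%d monomers)\n%s\n",
              x$strand_id, length(x$sugars), render_sequence(x)))
  invisible(x)
}
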