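si_cands <- function(senses) {
  x <- toy_candidates(senses, design_type = "SIRNA")
  attr(x, "k") <- 19L
  x
}

test_that("siRNA checklist: worked examples and bounds", {
  # 10.5% GC fails (a); pos 15-19 all A/T +5; pos3 A +1; pos10 T +1; the
  # ATTT(7-10)/AAAT(14-17) inverted repeat forms a 4-bp stem with a 3-nt
  # loop, so the no-stem bonus does not apply
  c1 <- sirna_point_score(si_cands("TAAGATATTTAGTAAATTT"))
  expect_identical(c1$sirna_score, 7L)
  expect_identical(c1$sirna_score, oracle_sirna_score("TAAGATATTTAGTAAATTT"))
  # all-G: every bonus but the no-stem one fails, two penalties, floored at 0
  c2 <- sirna_point_score(si_cands(strrep("G", 19)))
  expect_identical(c2$sirna_score, 0L)
  # constructed maximum: GC in range, A/T tail, A at 3 and 19, T at 10, no stem
  top <- "GCAGGGCGCTTTTTATTTA"
  stopifnot(gc_content(top) >= 30, gc_content(top) <= 52)
  c3 <- sirna_point_score(si_cands(top))
  expect_identical(c3$sirna_score, 10L)
})

test_that("siRNA score equals the checklist oracle on random 19-mers and stays in [0,10]", {
  set.seed(61)
  senses <- vapply(1:300, function(i) random_seq(19), character(1))
  got <- sirna_point_score(si_cands(senses))$sirna_score
  want <- vapply(senses, oracle_sirna_score, integer(1), USE.NAMES = FALSE)
  expect_identical(got, want)
  expect_true(all(got >= 0 & got <= 10))
})

test_that("siRNA score is NA for wrong k or ambiguity, errors for ASO input", {
  c20 <- toy_candidates(strrep("A", 20), design_type = "SIRNA")
  expect_true(is.na(sirna_point_score(c20)$sirna_score))
  cN <- si_cands(paste0(strrep("A", 18), "N"))
  expect_true(is.na(sirna_point_score(cN)$sirna_score))
  expect_error(sirna_point_score(toy_candidates(strrep("A", 19), "ASO")),
               class = "oligofunnel_design_type")
})

test_that("ASO score combines affinity, motif and self-structure terms", {
  base <- toy_candidates(c("AGTCAGTCAGTCAGTCAGTC"))
  mk <- function(dg, self = 0, hp = 0, anti = NULL) {
    x <- base
    if (!is.null(anti)) x$antisense_seq <- anti
    x$duplex_dg37 <- dg; x$self_dimer_dg37 <- self; x$hairpin_stem_max <- hp
    x
  }
  # strong binder, no penalties -> 1.0 (clamped top)
  expect_equal(aso_score(mk(-25))$aso_score, 1.0)
  expect_equal(aso_score(mk(-30))$aso_score, 1.0)
  # same but carrying a GGGG run -> 1.0 - 1.0
  expect_equal(aso_score(mk(-25, anti = "AGTCAGTCGGGGAGTCAGTC"))$aso_score, 0.0)
  # weak binder, clean -> 0 (clamped bottom)
  expect_equal(aso_score(mk(-10))$aso_score, 0.0)
  # mid-range affinity is linear
  expect_equal(aso_score(mk(-17.5))$aso_score, 0.5)
  # self-structure liabilities each cost 0.5
  expect_equal(aso_score(mk(-25, self = -9))$aso_score, 0.5)
  expect_equal(aso_score(mk(-25, self = -9, hp = 6))$aso_score, 0.0)
  expect_error(aso_score(base), class = "oligofunnel_dependency")
})

test_that("ASO score is monotone non-increasing in matched motif count and bounded", {
  runs <- c("GGGG", "AAAA", "TTTT", "CCCC")
  spacer <- "AGTC"
  for (n_mot in 0:4) {
    anti <- paste0(paste(runs[seq_len(n_mot)], collapse = spacer),
                   strrep(spacer, 3))
    x <- toy_candidates("AGTCAGTCAGTCAGTCAGTC")
    x$antisense_seq <- anti
    x$duplex_dg37 <- -25; x$self_dimer_dg37 <- 0; x$hairpin_stem_max <- 0
    sc <- aso_score(x)$aso_score
    expect_gte(sc, -2); expect_lte(sc, 1)
    if (n_mot == 0) prev <- sc
    expect_lte(sc, prev)
    prev <- sc
  }
})

test_that("composite score is linear in the weights and strict about properties", {
  x <- toy_candidates(c("ACGTACGTAC", "GGGGGGGGGG"))
  x$a <- c(3, 1); x$b <- c(4, 2)
  expect_equal(composite_score(x, list(a = 1))$composite, x$a)
  expect_equal(composite_score(x, list())$composite, c(0, 0))
  expect_equal(composite_score(x, list(a = 2, b = -1))$composite, c(2, 0))
  # linearity: w1 + w2 scores add
  s1 <- composite_score(x, list(a = 1.5))$composite
  s2 <- composite_score(x, list(b = 2))$composite
  s12 <- composite_score(x, list(a = 1.5, b = 2))$composite
  expect_equal(s12, s1 + s2)
  expect_error(composite_score(x, list(missing_prop = 1)),
               class = "oligofunnel_named_property")
  x$txt <- c("u", "v")
  expect_error(composite_score(x, list(txt = 1)),
               class = "oligofunnel_named_property")
})

test_that("efficacy scorer is pluggable", {
  x <- si_cands(c("TAAGATATTTAGTAAATTT"))
  def <- apply_efficacy_scorer(x, "default")
  expect_identical(def$sirna_score, 7L)
  custom <- function(cands) { cands$sirna_score <- 99; cands }
  expect_identical(apply_efficacy_scorer(x, custom)$sirna_score, 99)
  expect_error(apply_efficacy_scorer(x, "svm"), class = "oligofunnel_config")
})
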