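# a hand-built 10-candidate toy: 2 SNP carriers, 2 GGGG carriers (in the
# antisense compound), 1 heavy perfect off-target, 5 clean
funnel_toy <- function() {
  senses <- c("ATCGATCGATCGATCGATC",  # 1 clean
              "CATCGATTACGGATCGTAC",  # 2 snp
              "ATATCCCCGGCGCGATTAT",  # 3 motif: antisense has GGGG (sense CCCC)
              "TTACGCATTGCAATCGGCA",  # 4 clean
              "GCATTACGGATTTACGGAT",  # 5 snp
              "TACCCCATTAGCATTAGCA",  # 6 motif via antisense GGGG
              "AGCATTACGATCGGCATTA",  # 7 offtarget
              "CGATTACGGCATTAACGGA",  # 8 clean
              "TAGCATAACGATCAGCATC",  # 9 clean
              "ATCGGATCAACGATTAGCA")  # 10 clean
  x <- toy_candidates(senses, design_type = "ASO")
  x$snp_count <- c(0, 1, 0, 0, 2, 0, 0, 0, 0, 0)
  x$cdna_mm0 <- c(0, 0, 0, 0, 0, 0, 3, 0, 0, 0)
  x
}

test_that("funnel accounting: 5 survive, rejection labels match the hand count", {
  x <- funnel_toy()
  stopifnot(grepl("GGGG", x$antisense_seq[3]), grepl("GGGG", x$antisense_seq[6]),
            sum(grepl("GGGG|TTTT", x$antisense_seq)) == 2)
  res <- apply_filters(x, selection_config(n_select = 3))
  expect_length(res$selected, 5)
  expect_identical(res$selected, x$oligo_id[c(1, 4, 8, 9, 10)])
  expect_identical(sort(names(res$rejected)), sort(x$oligo_id[c(2, 3, 5, 6, 7)]))
  expect_identical(res$rejected[[x$oligo_id[2]]], "snp")
  expect_identical(res$rejected[[x$oligo_id[3]]], "motif")
  expect_identical(res$rejected[[x$oligo_id[7]]], "offtarget")
  # survivors + rejected == input
  expect_equal(length(res$selected) + length(res$rejected), nrow(x))
})

test_that("a candidate failing several filters carries all reasons, in order", {
  x <- funnel_toy()
  x$snp_count[3] <- 1      # candidate 3 now fails snp AND motif
  res <- apply_filters(x, selection_config())
  expect_identical(res$rejected[[x$oligo_id[3]]], c("snp", "motif"))
})

test_that("disabled filters reject nothing; missing property is a config error", {
  x <- funnel_toy()
  off <- selection_config(filter_snps = FALSE, motif_filters = list(),
                          max_perfect_offtargets = NULL)
  expect_length(apply_filters(x, off)$selected, nrow(x))

  y <- funnel_toy(); y$snp_count <- NULL
  err <- expect_error(apply_filters(y, selection_config()),
                      class = "oligofunnel_config")
  expect_match(conditionMessage(err), "snp_count")
})

test_that("filtering is idempotent", {
  x <- funnel_toy()
  cfg <- selection_config()
  first <- apply_filters(x, cfg)
  surv <- x[x$oligo_id %in% first$selected, ]
  second <- apply_filters(surv, cfg)
  expect_length(second$rejected, 0)
  expect_identical(second$selected, first$selected)
})

test_that("conservation and score filters engage when configured", {
  x <- funnel_toy()
  x$conserved_mouse <- c(rep(TRUE, 9), FALSE)
  x$aso_score <- c(0.9, rep(0.8, 8), 0.1)
  cfg <- selection_config(require_conserved_species = "mouse",
                          min_score = list(property = "aso_score", min = 0.5))
  res <- apply_filters(x, cfg)
  expect_identical(res$rejected[[x$oligo_id[10]]], c("conservation", "score"))
})

test_that("diversity pick: endpoint law, n >= survivors, determinism", {
  x <- toy_candidates(c("ACGTACGTAC", "GTACGTACGT", "TACGTACGTA"))
  x$start <- c(0L, 10L, 20L); x$end <- x$start + 10L
  picked <- diversity_pick(x, 2)
  expect_identical(picked, x$oligo_id[c(1, 3)])   # starts 0 and 20
  expect_identical(diversity_pick(x, 5), x$oligo_id)
  # input order does not matter (processing is start-sorted)
  expect_identical(diversity_pick(x[c(3, 1, 2), ], 2), picked)
})

test_that("greedy spread achieves at least half the optimal min-gap (exhaustive)", {
  set.seed(71)
  starts <- sort(sample(0:400, 12))
  x <- toy_candidates(vapply(1:12, function(i) random_seq(10), character(1)))
  x$start <- starts; x$end <- starts + 10L
  n_sel <- 4
  picked <- diversity_pick(x, n_sel)
  got_gap <- min(diff(sort(x$start[match(picked, x$oligo_id)])))
  combos <- utils::combn(12, n_sel)
  best_gap <- max(apply(combos, 2, function(ix) min(diff(starts[ix]))))
  expect_gte(got_gap, best_gap / 2)
})

test_that("select_oligos annotates selected flags and reasons for export", {
  x <- funnel_toy()
  res <- select_oligos(x, selection_config(n_select = 3))
  expect_s3_class(res, "selection_result")
  expect_length(res$selected, 3)
  expect_equal(sum(res$candidates$selected), 3)
  expect_identical(res$candidates$reject_reasons[2], "snp")
  expect_true(all(res$candidates$selected[res$candidates$reject_reasons != ""] == 0))
  # empty survivors: empty result, no error
  all_snp <- x; all_snp$snp_count <- 1
  res2 <- select_oligos(all_snp, selection_config())
  expect_length(res2$selected, 0)
})
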