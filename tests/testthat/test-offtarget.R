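make_db <- function(seqs, genes = paste0("G", seq_along(seqs))) {
  txs <- lapply(seq_along(seqs), function(i)
    transcript(paste0("X", i), seqs[i], gene_id = genes[i]))
  names(txs) <- paste0("X", seq_along(seqs))
  txs
}

test_that("search finds exact, 1-mismatch, and never >max_mm occurrences", {
  db <- make_db("ACGTACGTACGTACGTACGTACGT")
  idx <- build_index(db)
  q <- "ACGTACGTACGT"                      # occurs at offsets 0,4,8,12 (mm0)
  hits <- search_index(idx, q, 0)
  expect_identical(hits$offset, c(0L, 4L, 8L, 12L))
  expect_true(all(hits$mismatches == 0))

  q1 <- "ACGTACTTACGT"                     # one substitution
  h1 <- search_index(idx, q1, 2)
  expect_true(any(h1$mismatches == 1))

  q3 <- "TTTTACGTACGT"                     # >2 differences at offset 0
  h3 <- search_index(idx, q3, 2)
  expect_false(any(h3$offset == 0 & h3$mismatches <= 2 &
                     hamming(q3, substr(db$X1$sequence, 1, 12)) > 2))
})

test_that("all-N query yields no hits; short query errors; empty db errors", {
  db <- make_db("ACGTACGTACGTACGTACGT")
  idx <- build_index(db)
  expect_equal(nrow(search_index(idx, strrep("N", 12), 2)), 0)
  expect_error(search_index(idx, "ACGTACG", 2),
               class = "oligofunnel_query_too_short")
  expect_error(build_index(list()), class = "oligofunnel_empty_database")
})

test_that("pigeonhole search equals the linear-algebra oracle on random data", {
  set.seed(31)
  texts <- vapply(1:12, function(i) random_seq(sample(150:400, 1)), character(1))
  # salt a few texts with near-copies of coming queries
  queries <- vapply(1:40, function(i) random_seq(19), character(1))
  for (i in 1:10) {
    q <- queries[i]
    mut <- sample(0:2, 1)
    planted <- q
    if (mut > 0) {
      pos <- sample(19, mut)
      b <- strsplit(planted, "")[[1]]
      for (p in pos) b[p] <- sample(setdiff(c("A","C","G","T"), b[p]), 1)
      planted <- paste(b, collapse = "")
    }
    t <- sample(12, 1)
    at <- sample(nchar(texts[t]) - 19, 1)
    substr(texts[t], at, at + 18) <- planted
  }
  idx <- build_index(make_db(texts))
  got <- search_index(idx, queries, 2)
  want <- oracle_search(queries, texts, 2)
  got_cmp <- data.frame(query_idx = got$query_idx,
                        text_idx = match(got$transcript_id, paste0("X", 1:12)),
                        offset = got$offset, mismatches = got$mismatches)
  rownames(got_cmp) <- rownames(want) <- NULL
  expect_equal(got_cmp[order(got_cmp$query_idx, got_cmp$text_idx, got_cmp$offset), ],
               want[order(want$query_idx, want$text_idx, want$offset), ],
               ignore_attr = TRUE)
})

test_that("search agrees with Biostrings on a tiny fixture", {
  set.seed(32)
  text <- random_seq(300)
  q <- substr(text, 101, 119)
  idx <- build_index(make_db(text))
  got <- search_index(idx, q, 2)
  ref <- Biostrings::matchPattern(q, Biostrings::DNAString(text),
                                  max.mismatch = 2, with.indels = FALSE)
  expect_setequal(got$offset, Biostrings::start(ref) - 1L)
})

test_that("gene summaries use min mismatch, exclude target, ignore decoy order", {
  set.seed(33)
  target <- transcript("T1", random_seq(200), gene_id = "G1")
  win <- substr(target$sequence, 51, 69)
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  mm2 <- win
  substr(mm2, 3, 3) <- flip(substr(mm2, 3, 3))
  substr(mm2, 9, 9) <- flip(substr(mm2, 9, 9))
  stopifnot(hamming(win, mm2) == 2L)
  decoy1 <- transcript("D1", paste0(random_seq(40), win, random_seq(40)),
                       gene_id = "GD1")   # mm0 copy
  decoy1b <- transcript("D1b", paste0(win, random_seq(60)), gene_id = "GD1")
  decoy2 <- transcript("D2", paste0(random_seq(20), mm2, random_seq(70)),
                       gene_id = "GD2")   # mm2 copy

  for (ord in list(c(1, 2, 3, 4), c(4, 3, 2, 1), c(2, 4, 1, 3))) {
    db <- list(target, decoy1, decoy1b, decoy2)[ord]
    names(db) <- vapply(db, `[[`, character(1), "transcript_id")
    idx <- build_index(db)
    s <- summarize_hits(search_index(idx, win, 2), "G1")
    # GD1 has two transcripts with mm0 hits -> one gene at level 0
    expect_identical(unname(s), c(1L, 0L, 1L))
  }

  # database containing only the target gene: all zeros
  own <- build_index(list(T1 = target))
  s0 <- summarize_hits(search_index(own, win, 2), "G1")
  expect_identical(unname(s0), c(0L, 0L, 0L))
})

test_that("irrelevant decoys never change summaries", {
  set.seed(34)
  target <- transcript("T1", random_seq(120), gene_id = "G1")
  cands <- enumerate_candidates(target, 19, "ASO")
  near <- transcript("D1", paste0(random_seq(10), substr(target$sequence, 21, 39),
                                  random_seq(50)), gene_id = "GD1")
  base_db <- list(T1 = target, D1 = near)
  far <- transcript("DF", strrep("AC", 50), gene_id = "GDF")  # distance >2 from all
  q <- cands$sense_seq
  s1 <- summarize_hits(search_index(build_index(base_db), q[21], 2), "G1")
  expect_equal(nrow(search_index(build_index(list(DF = far)), q[21], 2)), 0)
  s2 <- summarize_hits(search_index(build_index(c(base_db, list(DF = far))), q[21], 2), "G1")
  expect_identical(s1, s2)
})

test_that("offtarget_profile routes strands and databases per design type", {
  set.seed(35)
  target <- transcript("T1", random_seq(100), gene_id = "G1")
  cands_aso <- enumerate_candidates(target, 20, "ASO")
  win <- cands_aso$sense_seq[11]
  decoy <- transcript("D1", paste0(random_seq(30), win, random_seq(30)),
                      gene_id = "GD1")
  cdna <- build_index(list(T1 = target, D1 = decoy), "cdna")
  gene <- build_index(list(G = transcript("G1.gene", paste0(target$sequence,
                                                            random_seq(50)),
                                          gene_id = "G1"),
                           D1 = decoy), "gene")
  prof <- offtarget_profile(cands_aso, cdna, gene)
  expect_equal(prof$cdna_mm0[11], 1)            # the decoy copy
  expect_equal(prof$gene_mm0[11], 1)            # decoy in gene db; own gene excluded
  expect_true(all(prof$cdna_mm0[!seq_len(nrow(prof)) %in% 11] <= 1))
  expect_error(offtarget_profile(cands_aso, cdna, NULL),
               class = "oligofunnel_config")

  cands_si <- enumerate_candidates(target, 19, "SIRNA")
  own_only <- build_index(list(T1 = target), "cdna")
  prof_si <- offtarget_profile(cands_si, own_only)
  expect_true(all(prof_si$cdna_mm0 == 0 & prof_si$cdna_mm1 == 0 &
                    prof_si$cdna_mm2 == 0))
  expect_true(all(prof_si$cdna_pass_mm0 == 0))
  expect_true(all(c("cdna_pass_mm0", "cdna_pass_mm1", "cdna_pass_mm2") %in%
                    names(prof_si)))
})
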