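test_that("gene assembly: transcript = exons, junctions at cumulative ends", {
  spec <- fixture_spec(rng_seed = 7, n_exons = 3, exon_len_range = c(50, 80),
                       intron_len_range = c(30, 60))
  g <- make_gene(spec)
  widths <- g$exons$end - g$exons$start
  expect_equal(nchar(g$primary$sequence), sum(widths))
  expect_identical(g$primary$exon_ends, cumsum(widths)[-3])
  # the spliced transcript is the concatenation of the gene's exon pieces
  expect_true(nchar(g$gene$sequence) > nchar(g$primary$sequence))
  expect_identical(substr(g$gene$sequence, 1, widths[1]),
                   substr(g$primary$sequence, 1, widths[1]))

  g1 <- make_gene(fixture_spec(rng_seed = 7, n_exons = 1))
  expect_identical(g1$gene$sequence, g1$primary$sequence)
  expect_length(g1$primary$exon_ends, 0)
})

test_that("fixture generation is byte-deterministic under the seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  spec <- fixture_spec(rng_seed = 99, n_snps = 4,
                       planted_offtargets = list(list(decoy = 1, mismatches = 1,
                                                      start = 10)))
  write_fixture_workspace(d1, spec)
  write_fixture_workspace(d2, spec)
  for (f in c("primary.fasta", "cdna.fasta", "gene.fasta", "exons.bed", "snps.vcf"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("orthologs: rate 0 identical, rate 1 disjoint, empirical rate within 3 sigma", {
  g <- make_gene(fixture_spec(rng_seed = 5, n_exons = 4,
                              exon_len_range = c(600, 700)))
  p <- g$primary
  spec <- fixture_spec(rng_seed = 5,
                       ortholog_species = c(same = 0, far = 1, mouse = 0.05))
  orths <- make_orthologs(p, spec)
  expect_identical(orths[[paste0("T1_same")]]$sequence, p$sequence)
  L <- nchar(p$sequence)
  mism <- function(o) hamming(p$sequence, o$sequence)
  expect_equal(mism(orths$T1_far), L)
  rate <- mism(orths$T1_mouse) / L
  sigma <- sqrt(0.05 * 0.95 / L)
  expect_lt(abs(rate - 0.05), 3 * sigma)
})

test_that("planted off-targets are recovered at exactly the planted level", {
  spec <- fixture_spec(rng_seed = 13, n_exons = 2, exon_len_range = c(200, 250),
                       n_decoy_genes = 5, decoy_len = 600,
                       planted_offtargets = list(
                         list(decoy = 1, mismatches = 0, start = 50),
                         list(decoy = 2, mismatches = 1, start = 50),
                         list(decoy = 3, mismatches = 2, start = 50)))
  g <- make_gene(spec)
  db <- make_offtarget_db(g$primary, spec)
  expect_identical(names(db)[1], "T1")
  idx <- build_index(db)
  win <- substr(g$primary$sequence, 51, 69)
  s <- summarize_hits(search_index(idx, win, 2), "G1")
  expect_identical(unname(s), c(1L, 1L, 1L))

  expect_error(make_offtarget_db(g$primary,
                                 fixture_spec(planted_offtargets = list(
                                   list(decoy = 1, mismatches = 25, start = 0)))),
               class = "oligofunnel_fixture_spec")
})

test_that("generated SNPs sit on the transcript with matching reference alleles", {
  g <- make_gene(fixture_spec(rng_seed = 3))
  spec <- fixture_spec(rng_seed = 3, n_snps = 8)
  snps <- make_snps(g$primary, spec)
  expect_equal(nrow(snps), 8)
  expect_false(any(duplicated(snps$pos)))
  for (i in seq_len(nrow(snps)))
    expect_identical(substr(g$primary$sequence, snps$pos[i], snps$pos[i]),
                     snps$ref_allele[i])
  # zero-SNP spec gives a parseable header-only VCF
  d <- withr::local_tempdir()
  write_fixture_workspace(d, fixture_spec(rng_seed = 3, n_snps = 0))
  expect_equal(nrow(read_snps(file.path(d, "snps.vcf"))), 0)
})

test_that("every generated file parses cleanly through the readers", {
  d <- withr::local_tempdir()
  spec <- fixture_spec(rng_seed = 17, n_snps = 5, n_splice_variants = 2,
                       ortholog_species = c(mouse = 0.05, rat = 0.1))
  paths <- write_fixture_workspace(d, spec, design_type = "SIRNA")
  prim <- read_fasta(paths$primary_fasta)
  expect_gte(length(prim), 4)           # primary + 2 variants + 2 orthologs
  expect_identical(prim[[1]]$transcript_id, "T1")
  cdna <- read_fasta(paths$cdna_fasta)
  expect_equal(length(cdna), 1 + spec$n_decoy_genes)
  gene <- read_fasta(paths$gene_fasta)
  expect_identical(gene[[1]]$transcript_id, "G1.gene")
  ex <- read_exons(paths$exons)
  expect_identical(ex$T1, make_gene(spec)$primary$exon_ends)
  snps <- read_snps(paths$vcf, prim)
  expect_equal(nrow(snps), 5)
  cfg <- read_run_config(paths$config)
  expect_identical(cfg$design_type, "SIRNA")
  expect_identical(cfg$k, 19L)
})
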