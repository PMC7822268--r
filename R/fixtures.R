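## Seeded synthetic-data generator: produces every input the pipeline
## consumes (gene + transcript FASTA, exon BED, ortholog and decoy
## databases, SNP VCF, run config), standing in for online sequence
## retrieval so complete workflows run offline and deterministically.
##
## A single integer seed fans out to per-component child seeds by a fixed
## derivation (seed combined with a component-tag hash), so adding one
## component never perturbs another's random stream.

## deterministic child seed below 2^31
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc_bias = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc_bias) / 2, gc_bias / 2, gc_bias / 2,
                        (1 - gc_bias) / 2)),
        collapse = "")
}

## substitute exactly `at` positions (or each position w.p. rate) with a
## different base
mutate_bases <- function(seq, positions) {
  b <- strsplit(seq, "")[[1]]
  for (p in positions)
    b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
  paste(b, collapse = "")
}

#' Specification of a synthetic design workspace
#'
#' @param rng_seed Master seed; all outputs are byte-reproducible from it.
#' @param n_exons Number of exons in the synthetic gene.
#' @param exon_len_range,intron_len_range Length ranges (nt), inclusive.
#' @param n_splice_variants Number of exon-skipping splice variants.
#' @param ortholog_species Named numeric vector/list: species ->
#'   per-base substitution rate in `[0, 1]`.
#' @param n_decoy_genes,decoy_len Off-target decoy count and length (nt).
#' @param n_snps Number of SNPs planted on the primary transcript.
#' @param planted_offtargets List of `list(decoy =, mismatches =, start =,
#'   len =)` entries: copy the primary-transcript window starting at
#'   0-based `start` (length `len`, default 19) into the given decoy with
#'   exactly `mismatches` substitutions.
#' @param gc_bias Base composition knob (probability of G or C).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(rng_seed = 1L, n_exons = 3L,
                         exon_len_range = c(150L, 400L),
                         intron_len_range = c(100L, 300L),
                         n_splice_variants = 1L,
                         ortholog_species = c(mouse = 0.05),
                         n_decoy_genes = 10L, decoy_len = 1000L,
                         n_snps = 5L, planted_offtargets = list(),
                         gc_bias = 0.5) {
  rates <- unlist(ortholog_species)
  if (length(rates) && (any(rates < 0) || any(rates > 1)))
    of_stop("ortholog substitution rates must lie in [0, 1]", "fixture_spec")
  if (any(c(n_exons, n_splice_variants, n_decoy_genes, n_snps) < 0))
    of_stop("fixture counts must be >= 0", "fixture_spec")
  structure(list(rng_seed = as.integer(rng_seed), n_exons = as.integer(n_exons),
                 exon_len_range = as.integer(exon_len_range),
                 intron_len_range = as.integer(intron_len_range),
                 n_splice_variants = as.integer(n_splice_variants),
                 ortholog_species = rates,
                 n_decoy_genes = as.integer(n_decoy_genes),
                 decoy_len = as.integer(decoy_len),
                 n_snps = as.integer(n_snps),
                 planted_offtargets = planted_offtargets,
                 gc_bias = gc_bias),
            class = "fixture_spec")
}

#' Generate the synthetic gene, primary transcript and exon structure
#'
#' The unspliced gene is a concatenation of seeded random exons and
#' introns; the primary transcript concatenates the exons, with junction
#' offsets at the cumulative exon ends.
#'
#' @param spec A [fixture_spec()].
#' @return List with `gene` (unspliced [transcript] record), `primary`
#'   (spliced primary transcript), and `exons` (data frame of 0-based
#'   half-open exon intervals in transcript coordinates, for BED export).
#' @export
make_gene <- function(spec) {
  with_seed(derive_seed(spec$rng_seed, "gene"), {
    ne <- max(spec$n_exons, 1L)
    exon_len <- sample(spec$exon_len_range[1]:spec$exon_len_range[2], ne,
                       replace = TRUE)
    intron_len <- if (ne > 1L)
      sample(spec$intron_len_range[1]:spec$intron_len_range[2], ne - 1L,
             replace = TRUE) else integer()
    exons <- vapply(exon_len, random_dna, character(1), gc_bias = spec$gc_bias)
    introns <- vapply(intron_len, random_dna, character(1), gc_bias = spec$gc_bias)
    pieces <- character(2L * ne - 1L)
    pieces[seq(1L, 2L * ne - 1L, by = 2L)] <- exons
    if (ne > 1L) pieces[seq(2L, 2L * ne - 2L, by = 2L)] <- introns
    gene_seq <- paste(pieces, collapse = "")
    tx_seq <- paste(exons, collapse = "")
    ends <- cumsum(exon_len)
    primary <- transcript("T1", tx_seq, gene_id = "G1", species = "human",
                          exon_ends = ends[-ne], is_primary = TRUE)
    list(gene = transcript("G1.gene", gene_seq, gene_id = "G1", species = "human"),
         primary = primary,
         exons = data.frame(transcript_id = "T1",
                            start = c(0L, ends[-ne]), end = ends))
  })
}

#' Generate exon-skipping splice variants
#'
#' Variant `i` drops one internal exon (cyclically) from the primary
#' transcript; with fewer than three exons, variants are 3'-truncations.
#'
#' @param gene Output of [make_gene()].
#' @param spec A [fixture_spec()].
#' @return List of [transcript] objects (`T2`, `T3`, ...).
#' @export
make_splice_variants <- function(gene, spec) {
  if (spec$n_splice_variants == 0L) return(list())
  ex <- gene$exons
  seqs <- substring(gene$primary$sequence, ex$start + 1L, ex$end)
  out <- list()
  for (v in seq_len(spec$n_splice_variants)) {
    keep <- if (nrow(ex) >= 3L) {
      setdiff(seq_len(nrow(ex)), 1L + (v - 1L) %% (nrow(ex) - 2L) + 1L)
    } else seq_len(max(nrow(ex) - 1L, 1L))
    vseq <- paste(seqs[keep], collapse = "")
    id <- sprintf("T%d", v + 1L)
    out[[id]] <- transcript(id, vseq, gene_id = "G1", species = "human")
  }
  out
}

#' Generate ortholog transcripts
#'
#' Per species, each base of the primary transcript is substituted
#' independently at the configured rate, never to the same base.
#'
#' @param primary The primary [transcript].
#' @param spec A [fixture_spec()].
#' @return Named list of [transcript] objects
#'   (`<primary_id>_<species>`).
#' @export
make_orthologs <- function(primary, spec) {
  out <- list()
  for (sp in names(spec$ortholog_species)) {
    rate <- spec$ortholog_species[[sp]]
    seq <- with_seed(derive_seed(spec$rng_seed, paste0("ortholog_", sp)), {
      hit <- which(stats::runif(nchar(primary$sequence)) < rate)
      mutate_bases(primary$sequence, hit)
    })
    id <- paste0(primary$transcript_id, "_", sp)
    out[[id]] <- transcript(id, seq, gene_id = paste0(primary$gene_id, "_", sp),
                            species = sp)
  }
  out
}

#' Generate the off-target decoy database
#'
#' Random decoy transcripts plus, where requested, planted copies of
#' primary-transcript windows carrying exactly the requested number of
#' mismatches at seeded positions. The target gene's own transcript is
#' always included (off-target counting must exclude it).
#'
#' @param primary The primary [transcript].
#' @param spec A [fixture_spec()].
#' @return Named list of [transcript] objects: the target transcript
#'   followed by decoys `D1..Dn` (genes `GD1..GDn`).
#' @export
make_offtarget_db <- function(primary, spec) {
  with_seed(derive_seed(spec$rng_seed, "offtarget_db"), {
    db <- stats::setNames(list(primary), primary$transcript_id)
    decoys <- vapply(seq_len(spec$n_decoy_genes), function(i)
      random_dna(spec$decoy_len, spec$gc_bias), character(1))
    for (plant in spec$planted_offtargets) {
      len <- plant$len %||% 19L
      if (plant$mismatches > len)
        of_stop("planted mismatch count exceeds the window length", "fixture_spec")
      window <- substr(primary$sequence, plant$start + 1L, plant$start + len)
      if (nchar(window) < len)
        of_stop("planted window extends past the primary transcript", "fixture_spec")
      if (plant$mismatches > 0L)
        window <- mutate_bases(window, sample(len, plant$mismatches))
      at <- sample(spec$decoy_len - len + 1L, 1L)
      d <- decoys[plant$decoy]
      decoys[plant$decoy] <- paste0(substr(d, 1L, at - 1L), window,
                                    substr(d, at + len, spec$decoy_len))
    }
    for (i in seq_len(spec$n_decoy_genes)) {
      id <- sprintf("D%d", i)
      db[[id]] <- transcript(id, decoys[i], gene_id = sprintf("GD%d", i),
                             species = "human")
    }
    db
  })
}

#' Generate SNPs on the primary transcript
#'
#' Distinct seeded positions; the reference allele always matches the
#' transcript base and the alternate is a random different base. IDs are
#' `rs1..rsN` in ascending position order.
#'
#' @param primary The primary [transcript].
#' @param spec A [fixture_spec()].
#' @return SNP data frame in the [read_snps()] layout.
#' @export
make_snps <- function(primary, spec) {
  L <- nchar(primary$sequence)
  if (spec$n_snps > L)
    of_stop("cannot place more SNPs than transcript positions", "fixture_spec")
  if (spec$n_snps == 0L)
    return(data.frame(transcript_id = character(), pos = integer(),
                      snp_id = character(), ref_allele = character(),
                      alt_alleles = I(list())))
  with_seed(derive_seed(spec$rng_seed, "snps"), {
    pos <- sort(sample(L, spec$n_snps))
    ref <- substring(primary$sequence, pos, pos)
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  character(1), USE.NAMES = FALSE)
    data.frame(transcript_id = rep(primary$transcript_id, spec$n_snps),
               pos = pos,
               snp_id = sprintf("rs%d", seq_len(spec$n_snps)),
               ref_allele = unname(ref),
               alt_alleles = I(as.list(alt)))
  })
}

write_vcf <- function(snps, path) {
  lines <- c("##fileformat=VCFv4.2",
             "##source=oligofunnel-fixtures",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   sep = "\t"))
  if (nrow(snps))
    lines <- c(lines, sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                              snps$transcript_id, snps$pos, snps$snp_id,
                              snps$ref_allele,
                              vapply(snps$alt_alleles, paste, character(1),
                                     collapse = ",")))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

write_bed <- function(exons, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("%s\t%d\t%d", exons$transcript_id, exons$start, exons$end),
             con, sep = "\n")
  invisible(path)
}

#' Write a complete synthetic design workspace
#'
#' Generates every pipeline input into `dir`: `primary.fasta` (primary +
#' splice variants + orthologs), `cdna.fasta` (target transcripts +
#' decoys), `gene.fasta` (unspliced gene + decoys), `exons.bed`,
#' `snps.vcf`, and a ready-to-run `config.yaml`.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [fixture_spec()].
#' @param design_type `"ASO"` or `"SIRNA"` for the written config.
#' @return Named list of written paths, invisibly.
#' @export
write_fixture_workspace <- function(dir, spec = fixture_spec(),
                                    design_type = c("ASO", "SIRNA")) {
  design_type <- match.arg(design_type)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gene <- make_gene(spec)
  variants <- make_splice_variants(gene, spec)
  orthologs <- make_orthologs(gene$primary, spec)
  cdna_db <- make_offtarget_db(gene$primary, spec)
  snps <- make_snps(gene$primary, spec)

  paths <- list(primary_fasta = file.path(dir, "primary.fasta"),
                cdna_fasta = file.path(dir, "cdna.fasta"),
                gene_fasta = file.path(dir, "gene.fasta"),
                exons = file.path(dir, "exons.bed"),
                vcf = file.path(dir, "snps.vcf"),
                config = file.path(dir, "config.yaml"))
  write_fasta(c(list(gene$primary), variants, orthologs), paths$primary_fasta)
  write_fasta(cdna_db, paths$cdna_fasta)
  write_fasta(c(list(gene$gene), cdna_db[-1L]), paths$gene_fasta)
  write_bed(gene$exons, paths$exons)
  write_vcf(snps, paths$vcf)
  cfg <- list(design_type = design_type,
              k = if (design_type == "ASO") 20L else 19L,
              max_mismatches = 2L,
              primary_id = gene$primary$transcript_id,
              rng_seed = spec$rng_seed,
              paths = list(primary_fasta = "primary.fasta",
                           cdna_fasta = "cdna.fasta",
                           gene_fasta = "gene.fasta",
                           exons = "exons.bed",
                           vcf = "snps.vcf"))
  yaml_text <- yaml::as.yaml(cfg)
  con <- file(paths$config, "wb")
  writeLines(yaml_text, con, sep = "")
  close(con)
  invisible(paths)
}
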