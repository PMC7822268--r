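## Readers and writers: FASTA transcript sets, BED/GFF3 exon structures in
## transcript coordinates, VCF SNPs (CHROM = transcript ID), YAML run
## configuration, and the annotated-candidate CSV.

#' Read a transcript FASTA file
#'
#' Headers follow the convention `>transcriptID|geneID|species`; `geneID`
#' defaults to the transcript ID and `species` to `"unknown"` when absent.
#' Sequences are uppercased and `U` is normalized to `T`. Record order is
#' preserved.
#'
#' @param path Path to a FASTA file (plain or gzip).
#' @param primary_id Optional transcript ID to flag as the primary target.
#' @return A named list of [transcript] objects (names = transcript IDs).
#' @export
read_fasta <- function(path, primary_id = NULL) {
  if (!file.exists(path)) of_stop(sprintf("FASTA file not found: %s", path), "io")
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  txs <- vector("list", length(set))
  ids <- character(length(set))
  for (i in seq_along(set)) {
    fields <- strsplit(sub("\\s.*$", "", headers[i]), "|", fixed = TRUE)[[1]]
    if (length(fields) < 1L || !nzchar(fields[1]))
      of_stop(sprintf("malformed FASTA header at record %d: '%s' (no transcript ID)",
                      i, headers[i]), "format")
    id <- fields[1]
    gene <- if (length(fields) >= 2L && nzchar(fields[2])) fields[2] else id
    species <- if (length(fields) >= 3L && nzchar(fields[3])) fields[3] else "unknown"
    if (id %in% ids[seq_len(i - 1L)])
      of_stop(sprintf("duplicate transcript_id '%s' at record %d", id, i),
              "duplicate_record")
    ids[i] <- id
    txs[[i]] <- transcript(id, as.character(set[[i]]), gene_id = gene,
                           species = species,
                           is_primary = !is.null(primary_id) && id == primary_id)
  }
  names(txs) <- ids
  txs
}

#' Write transcripts as FASTA
#'
#' Inverse of [read_fasta()]: headers are `>transcriptID|geneID|species`.
#'
#' @param transcripts List of [transcript] objects.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(transcripts, path, width = 70L) {
  lines <- unlist(lapply(transcripts, function(tx) {
    seq <- tx$sequence
    starts <- seq(1L, nchar(seq), by = width)
    c(sprintf(">%s|%s|%s", tx$transcript_id, tx$gene_id, tx$species),
      substring(seq, starts, pmin(starts + width - 1L, nchar(seq))))
  }), use.names = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read exon structures in transcript coordinates
#'
#' Accepts BED (0-based half-open) or GFF3 `exon` features (1-based
#' inclusive) whose seqid is the transcript ID. Exons of one transcript must
#' not overlap. The returned junction offsets are the cumulative exon end
#' positions (0-based offsets into the spliced transcript) excluding the
#' transcript end, sorted ascending — i.e. a single-exon transcript maps to
#' an empty vector.
#'
#' @param path Path to a BED or GFF3 file.
#' @param fmt `"auto"` (by extension), `"bed"` or `"gff3"`.
#' @return Named list: transcript_id -> integer vector of junction offsets.
#' @export
read_exons <- function(path, fmt = c("auto", "bed", "gff3")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) of_stop(sprintf("exon file not found: %s", path), "io")
  if (fmt == "auto")
    fmt <- if (grepl("\\.(gff3?|gtf)(\\.gz)?$", path, ignore.case = TRUE)) "gff3" else "bed"
  gr <- if (fmt == "bed") {
    rtracklayer::import(path, format = "BED")
  } else {
    g <- rtracklayer::import(path, format = "GFF3")
    if (!is.null(g$type)) g[tolower(as.character(g$type)) == "exon"] else g
  }
  out <- list()
  for (id in as.character(unique(GenomicRanges::seqnames(gr)))) {
    ex <- gr[as.character(GenomicRanges::seqnames(gr)) == id]
    o <- order(GenomicRanges::start(ex))
    s <- GenomicRanges::start(ex)[o]   # 1-based inclusive after import
    e <- GenomicRanges::end(ex)[o]
    if (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
      of_stop(sprintf("overlapping exons for transcript '%s' in %s", id, path),
              "format")
    ## 1-based inclusive end == 0-based exclusive offset of the junction
    out[[id]] <- as.integer(e[-length(e)])
  }
  out
}

#' Read SNPs from a VCF file
#'
#' CHROM holds the transcript ID and POS a 1-based transcript coordinate.
#' Only single-nucleotide variants are kept; indels are skipped with a
#' warning. Multi-allelic ALT fields are preserved as a list of alleles.
#' When `transcripts` is supplied, a reference allele that does not match
#' the transcript base triggers a warning (not an error).
#'
#' @param path Path to a VCF v4.x file.
#' @param transcripts Optional named list of [transcript] objects for
#'   reference-allele validation.
#' @return Data frame with columns `transcript_id`, `pos`, `snp_id`,
#'   `ref_allele` and list column `alt_alleles`, one row per kept record.
#' @export
read_snps <- function(path, transcripts = NULL) {
  if (!file.exists(path)) of_stop(sprintf("VCF file not found: %s", path), "io")
  raw <- readLines(path)
  n_data <- sum(!startsWith(raw, "#") & nzchar(raw))
  empty <- data.frame(transcript_id = character(), pos = integer(),
                      snp_id = character(), ref_allele = character(),
                      alt_alleles = I(list()))
  if (n_data == 0L) return(empty)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt_split <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",", fixed = TRUE)
  is_snv <- nchar(ref) == 1L & ref %in% c("A", "C", "G", "T") &
    vapply(alt_split, function(a) length(a) > 0L && all(nchar(a) == 1L & a %in% c("A", "C", "G", "T")),
           logical(1))
  if (any(!is_snv))
    of_warn(sprintf("skipped %d non-SNV record(s) in %s", sum(!is_snv), path),
            "indel_skipped")
  if (!any(is_snv)) return(empty)
  snps <- data.frame(transcript_id = unname(fix[is_snv, "CHROM"]),
                     pos = as.integer(fix[is_snv, "POS"]),
                     snp_id = unname(fix[is_snv, "ID"]),
                     ref_allele = unname(ref[is_snv]),
                     alt_alleles = I(unname(alt_split[is_snv])))
  if (!is.null(transcripts)) {
    for (i in seq_len(nrow(snps))) {
      tx <- transcripts[[snps$transcript_id[i]]]
      if (is.null(tx)) next
      base <- substr(tx$sequence, snps$pos[i], snps$pos[i])
      if (!identical(base, snps$ref_allele[i]))
        of_warn(sprintf("SNP %s: REF '%s' does not match transcript %s base '%s' at pos %d",
                        snps$snp_id[i], snps$ref_allele[i], snps$transcript_id[i],
                        base, snps$pos[i]),
                "ref_mismatch")
    }
  }
  snps
}

## ---- candidate CSV ------------------------------------------------------

## RFC 4180: quote a field only when it contains a delimiter, quote or newline
csv_quote <- function(x) {
  needs <- grepl('[",\n\r]', x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

## format one property column: doubles at 4 decimals, flags as 0/1, NA as ""
csv_cell <- function(v) {
  out <- if (is.logical(v)) {
    as.character(as.integer(v))
  } else if (is.double(v)) {
    sprintf("%.4f", v)
  } else {
    as.character(v)
  }
  out[is.na(v)] <- ""
  out
}

#' Write annotated candidates to CSV
#'
#' Emits the fixed core columns (`oligo_id`, `design_type`, `start_1based`,
#' `end_1based`, `sense_seq`, `antisense_seq`) followed by property columns.
#' Floating-point properties are printed with 4 decimals, flags as 0/1,
#' missing values as empty strings; line endings are LF and quoting follows
#' RFC 4180 (quotes only where needed).
#'
#' @param candidates A candidate table from [enumerate_candidates()].
#' @param path Output path.
#' @param columns Property columns to emit, in order; default all property
#'   columns in table order.
#' @return `path`, invisibly.
#' @export
write_candidates_csv <- function(candidates, path, columns = NULL) {
  core <- c("oligo_id", "design_type", "start_1based", "end_1based",
            "sense_seq", "antisense_seq")
  df <- data.frame(oligo_id = candidates$oligo_id,
                   design_type = candidates$design_type,
                   start_1based = candidates$start + 1L,
                   end_1based = candidates$end,   # 0-based exclusive == 1-based inclusive
                   sense_seq = candidates$sense_seq,
                   antisense_seq = candidates$antisense_seq,
                   stringsAsFactors = FALSE)
  if (is.null(columns))
    columns <- setdiff(names(candidates),
                       c("oligo_id", "design_type", "start", "end",
                         "sense_seq", "antisense_seq"))
  cells <- c(lapply(df, function(v) csv_quote(as.character(v))),
             lapply(columns, function(col) {
               if (col %in% names(candidates)) csv_quote(csv_cell(candidates[[col]]))
               else rep("", nrow(df))
             }))
  header <- paste(csv_quote(c(core, columns)), collapse = ",")
  rows <- do.call(paste, c(cells, sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n")
  invisible(path)
}

#' Read a candidate CSV written by [write_candidates_csv()]
#'
#' @param path Path to the CSV.
#' @return A data frame; core coordinate columns are integer.
#' @export
read_candidates_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

## ---- run configuration --------------------------------------------------

#' Default run configuration
#'
#' @param design_type `"ASO"` or `"SIRNA"`.
#' @return A `run_config` list with all defaults filled in.
#' @export
default_run_config <- function(design_type = c("ASO", "SIRNA")) {
  design_type <- match.arg(design_type)
  structure(list(
    design_type = design_type,
    k = if (design_type == "ASO") 20L else 19L,
    max_mismatches = 2L,
    add_tt_overhang = FALSE,
    primary_id = NULL,
    paths = list(primary_fasta = NULL, cdna_fasta = NULL, gene_fasta = NULL,
                 exons = NULL, vcf = NULL),
    efficacy_scorer = "default",
    selection = selection_config(),
    aso_scoring = list(a_min = 10, a_max = 25),
    weights = NULL,
    rng_seed = 1L
  ), class = "run_config")
}

#' Read a YAML run configuration
#'
#' Unspecified keys fall back to [default_run_config()] defaults. Relative
#' file paths are resolved against the directory containing the YAML file.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) of_stop(sprintf("config file not found: %s", path), "io")
  raw <- yaml::read_yaml(path)
  cfg <- default_run_config(toupper(raw$design_type %||% "ASO"))
  for (key in setdiff(names(raw), c("paths", "selection")))
    cfg[[key]] <- raw[[key]]
  if (!is.null(raw$paths)) cfg$paths <- utils::modifyList(cfg$paths, raw$paths)
  if (!is.null(raw$selection))
    cfg$selection <- do.call(selection_config, raw$selection)
  base <- dirname(normalizePath(path))
  cfg$paths <- lapply(cfg$paths, function(p) {
    if (is.null(p) || file.exists(p)) p else file.path(base, p)
  })
  validate_run_config(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_run_config <- function(cfg) {
  cfg$k <- as.integer(cfg$k)
  cfg$max_mismatches <- as.integer(cfg$max_mismatches)
  if (is.na(cfg$k) || cfg$k < 8L)
    of_stop("k must be an integer >= 8", "config")
  if (is.na(cfg$max_mismatches) || cfg$max_mismatches < 0L || cfg$max_mismatches > 2L)
    of_stop("max_mismatches must be between 0 and 2", "config")
  if (!cfg$design_type %in% c("ASO", "SIRNA"))
    of_stop("design_type must be 'ASO' or 'SIRNA'", "config")
  cfg
}
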