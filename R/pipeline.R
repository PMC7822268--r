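## Workflow orchestration: chain enumeration -> annotation -> off-target
## profiling -> thermodynamics/scoring -> selection -> CSV export from a
## single run configuration. Each stage logs candidate counts so the
## funnel accounting is visible; the whole chain is deterministic given
## (config, seed).

#' Run the complete design workflow
#'
#' Loads the configured inputs, enumerates all candidates over the primary
#' transcript, annotates them (GC, SNPs, exon junctions, conservation
#' against every other transcript in the primary FASTA), profiles
#' off-targets, computes thermodynamics and scores, runs the selection
#' funnel, and writes the annotated CSV.
#'
#' @param config A `run_config` (from [read_run_config()] or
#'   [default_run_config()]) or the path to a YAML config file.
#' @param output_csv Path for the exported CSV (default
#'   `oligos_<design>.csv` next to the config's primary FASTA).
#' @return A `pipeline_result` list: `candidates` (fully annotated table),
#'   `selection` (a `selection_result`), `csv_path`, `config`.
#' @export
run_pipeline <- function(config, output_csv = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- validate_run_config(config)
  p <- cfg$paths
  if (is.null(p$primary_fasta))
    of_stop("run_pipeline requires paths$primary_fasta", "prerequisite")

  ## --- load ---------------------------------------------------------
  transcripts <- read_fasta(p$primary_fasta, primary_id = cfg$primary_id)
  primary_id <- cfg$primary_id %||% transcripts[[1]]$transcript_id
  if (is.null(transcripts[[primary_id]]))
    of_stop(sprintf("primary transcript '%s' not found in %s",
                    primary_id, p$primary_fasta), "prerequisite")
  primary <- transcripts[[primary_id]]
  primary$is_primary <- TRUE
  if (!is.null(p$exons)) {
    junctions <- read_exons(p$exons)[[primary_id]]
    if (!is.null(junctions))
      primary <- transcript(primary$transcript_id, primary$sequence,
                            primary$gene_id, primary$species,
                            exon_ends = junctions, is_primary = TRUE)
  }
  snps <- if (!is.null(p$vcf)) read_snps(p$vcf, transcripts) else NULL
  of_log("load", n_transcripts = length(transcripts),
         primary = primary_id, L = nchar(primary$sequence),
         n_snps = if (is.null(snps)) 0L else nrow(snps))

  ## --- enumerate ----------------------------------------------------
  cands <- enumerate_candidates(primary, cfg$k, cfg$design_type,
                                add_tt_overhang = isTRUE(cfg$add_tt_overhang))
  of_log("enumerate", k = cfg$k, n_candidates = nrow(cands))

  ## --- annotate -----------------------------------------------------
  cands <- annotate_gc(cands)
  if (!is.null(snps)) cands <- annotate_snps(cands, snps)
  cands <- annotate_junction(cands, primary)
  others <- transcripts[names(transcripts) != primary_id]
  if (length(others))
    cands <- annotate_conservation(cands, others, cfg$max_mismatches)
  of_log("annotate", n_candidates = nrow(cands),
         n_other_transcripts = length(others))

  ## --- off-target ---------------------------------------------------
  if (!is.null(p$cdna_fasta)) {
    cdna_index <- build_index(read_fasta(p$cdna_fasta), "cdna")
    gene_index <- if (cfg$design_type == "ASO") {
      if (is.null(p$gene_fasta))
        of_stop("ASO design requires paths$gene_fasta (unspliced-gene database)",
                "prerequisite")
      build_index(read_fasta(p$gene_fasta), "gene")
    } else NULL
    cands <- offtarget_profile(cands, cdna_index, gene_index,
                               max_mm = cfg$max_mismatches,
                               target_gene_id = primary$gene_id)
    of_log("offtarget", cdna_db = length(cdna_index$sequences),
           gene_db = if (is.null(gene_index)) 0L else length(gene_index$sequences))
  }

  ## --- thermodynamics + scoring --------------------------------------
  if (cfg$design_type == "ASO") {
    cands <- thermo_profile(cands)
    cands <- aso_score(cands, a_min = cfg$aso_scoring$a_min,
                       a_max = cfg$aso_scoring$a_max)
  } else {
    cands <- apply_efficacy_scorer(cands, cfg$efficacy_scorer)
  }
  if (!is.null(cfg$weights)) cands <- composite_score(cands, cfg$weights)
  of_log("score", design = cfg$design_type)

  ## --- selection ----------------------------------------------------
  sel_cfg <- cfg$selection
  if (is.null(cands$snp_count)) sel_cfg$filter_snps <- FALSE
  if (is.null(cands$cdna_mm0)) sel_cfg$max_perfect_offtargets <- NULL
  result <- select_oligos(cands, sel_cfg)
  cands <- result$candidates

  ## --- export -------------------------------------------------------
  if (is.null(output_csv))
    output_csv <- file.path(dirname(p$primary_fasta),
                            sprintf("oligos_%s.csv", tolower(cfg$design_type)))
  write_candidates_csv(cands, output_csv)
  of_log("export", path = output_csv, n_rows = nrow(cands))

  structure(list(candidates = cands, selection = result,
                 csv_path = output_csv, config = cfg),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s | %d candidates | %d selected | %s\n",
              x$config$design_type, nrow(x$candidates),
              length(x$selection$selected), x$csv_path))
  invisible(x)
}

#' Generate a demo workspace and run it (command-line helpers)
#'
#' `cmd_fixtures()` writes a complete synthetic workspace (see
#' [write_fixture_workspace()]); `cmd_run()` executes the full workflow
#' from a YAML config. Both return an exit code (0 on success) so a thin
#' Rscript wrapper can expose them as shell subcommands.
#'
#' @param dir Workspace directory.
#' @param seed Master RNG seed for fixture generation.
#' @param design_type `"ASO"` or `"SIRNA"`.
#' @return Integer exit code, invisibly.
#' @export
cmd_fixtures <- function(dir, seed = 1L, design_type = "ASO") {
  paths <- write_fixture_workspace(dir, fixture_spec(rng_seed = seed),
                                   design_type = design_type)
  of_log("fixtures", dir = dir, seed = seed, config = paths$config)
  invisible(0L)
}

#' @rdname cmd_fixtures
#' @param config Path to a YAML run config.
#' @param output_csv Optional CSV output path.
#' @export
cmd_run <- function(config, output_csv = NULL) {
  res <- run_pipeline(config, output_csv)
  invisible(if (file.exists(res$csv_path)) 0L else 1L)
}
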