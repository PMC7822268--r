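# oligofunnel

Enumeration, annotation and selection of siRNAs and antisense
oligonucleotides (ASOs), as an offline R library with a thin command-line
front end.

## What it does, and for whom

Knocking down a gene with an siRNA or an RNase H-dependent ASO means
choosing a handful of sequences out of every possible k-mer tiling the
target transcript. oligofunnel is for computational biologists and
oligonucleotide chemists who want that choice to be explicit,
reproducible and scriptable:

1. **Enumerate** all `L - k + 1` candidate windows of the primary
   transcript (sense window = siRNA passenger; its reverse complement =
   the ASO / siRNA guide).
2. **Annotate** each candidate: GC content, SNP overlap, exon-junction
   spanning, conservation against splice variants and orthologs (minimum
   mismatches, capped at 2), nearest-neighbor duplex thermodynamics, and
   off-target counts — distinct genes hit at 0/1/2 mismatches, excluding
   the target gene, from a pigeonhole seed-and-verify search that is
   provably complete up to 2 mismatches (no aligner dependency).
3. **Score**: a transparent point-based siRNA checklist (0–10, Reynolds
   style), an ASO score combining target affinity
   (`clamp((-ΔG37 - 10)/15, 0, 1)`) with motif and self-structure
   penalties, and arbitrary user-weighted composites.
4. **Select**: hard filters (SNPs, poly-G/poly-T motifs, perfect
   off-target matches, conservation, score) with full per-candidate
   rejection-reason accounting, then a greedy max–min positional
   diversity pick.
5. **Export** everything as a stable CSV; represent chemically modified
   designs (LNA gapmers, phosphorothioate backbones, 2'OMe, 5mC) in a
   HELM-style monomer notation with text renderings.

The core quantities are standard: duplex stability is the nearest-neighbor
sum `ΔG37 = ΔG_init + Σ stacks (+ terminal terms)` over shipped DNA:DNA
and DNA:RNA parameter tables, and the two-state melting temperature is
`Tm = 1000·ΔH / (ΔS + R·ln(CT/4)) − 273.15` with an optional
`16.6·log10([Na+])` salt correction.

All inputs are plain files — FASTA (`>transcriptID|geneID|species`),
BED/GFF3 exon structures in transcript coordinates, VCF SNPs with CHROM =
transcript ID, YAML config — and a seeded fixture generator synthesizes a
complete, byte-reproducible demo workspace, so nothing here needs network
access.

## Worked example

```r
library(oligofunnel)

ws <- file.path(tempdir(), "demo")
paths <- write_fixture_workspace(ws, fixture_spec(rng_seed = 42),
                                 design_type = "SIRNA")
res <- run_pipeline(paths$config)
#> [INFO] load n_transcripts=3 primary=T1 L=922 n_snps=5
#> [INFO] enumerate k=19 n_candidates=904
#> [INFO] annotate n_candidates=904 n_other_transcripts=2
#> [INFO] offtarget cdna_db=11 gene_db=0
#> [INFO] score design=SIRNA
#> [INFO] select n_in=904 n_survivors=761 n_selected=10
#> [INFO] export path=/tmp/.../demo/oligos_sirna.csv n_rows=904
```

The 922-nt synthetic transcript yields 904 19-mer duplex candidates; 143
are rejected (SNP overlap, poly-G/poly-T motifs in the guide, or perfect
off-target genes in the 10-decoy cDNA database) and the diversity pick
keeps 10 spread along the transcript:

```r
res$candidates[res$candidates$selected == 1,
               c("oligo_id", "start", "sense_seq", "gc_percent",
                 "sirna_score", "cdna_mm0", "snp_count")][1:5, ]
#>  oligo_id start           sense_seq gc_percent sirna_score cdna_mm0 snp_count
#>      T1_1     0 CCGGCTGGCGACAGATATA   57.89474           7        0         0
#>     T1_57    56 TTGATATAAGGTCAGATAT   26.31579           4        0         0
#>    T1_113   112 ATGCTGGTTCGGACCATTC   52.63158           2        0         0
#>    T1_226   225 GTCGGACGGCTTATTAGTA   47.36842           7        0         0
#>    T1_338   337 TGGCTCACACCTCTTAGAA   47.36842           7        0         0
```

`sirna_score` is the 0–10 checklist score (GC window, 3' sense-end A/U
richness, structure, position-specific bases); `cdna_mm0` counts distinct
non-target genes with a perfect match to the guide's target site — 0 is
what you want. The full annotated table is also written as CSV.

A chemically modified version of a chosen compound — a classic gapmer
with three LNA wings on a fully phosphorothioated backbone:

```r
g <- gapmer("GCATTGGTATTCAGTGTGAT")
helm_write(g)
#> RNA1{[LR](G)[sP].[LR](C)[sP].[LR](A)[sP].[dR](T)[sP]. ... .[LR](T)}$$$$
render_sequence(g)
#> +G*+C*+A*t*t*g*g*t*a*t*t*c*a*g*t*g*t*+G*+A*+T
```

The same workflow runs from a shell via the bundled script
(`inst/cli/oligofunnel`): `oligofunnel fixtures --workspace ws --seed 1`
then `oligofunnel run --config ws/config.yaml`.

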