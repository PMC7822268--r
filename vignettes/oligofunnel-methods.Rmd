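---
title: "Designing siRNAs and antisense oligonucleotides with oligofunnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing siRNAs and antisense oligonucleotides with oligofunnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligofunnel)
```

## The design problem

Silencing a gene with a small interfering RNA (siRNA) or an RNase
H-dependent antisense oligonucleotide (ASO) starts from an embarrassment of
riches: a transcript of length $L$ offers $L - k + 1$ candidate oligos of
length $k$, and almost all of them are bad — they overlap polymorphic
sites, carry toxic sequence motifs, bind hundreds of unintended
transcripts, fold on themselves, or simply bind their target too weakly.
Rational design is therefore a funnel: enumerate everything, annotate each
candidate with the properties known to matter, and filter and rank until a
small, positionally diverse panel remains.

oligofunnel implements that funnel as an offline library. All inputs are
files (FASTA transcripts with `transcriptID|geneID|species` headers, BED or
GFF3 exon structures in transcript coordinates, VCF SNPs whose CHROM is the
transcript ID, a YAML run configuration); a seeded generator
(`write_fixture_workspace()`) can synthesize a complete workspace, so every
workflow in this vignette and in the test suite runs with no network
access.

## Enumeration and coordinates

`enumerate_candidates()` tiles the primary transcript with every window of
length $k$ (default 20 for ASOs, 19 for siRNAs). The window itself is the
*sense* sequence (the siRNA passenger); its reverse complement is the
compound — the ASO, or the siRNA guide. Internally all sequences live in
the DNA alphabet with 0-based half-open coordinates; RNA rendering
(`to_rna()`, `sirna_strands()`) and 1-based inclusive coordinates appear
only at output. `U` is normalized to `T` on load so search and
thermodynamics work over one canonical alphabet.

Ambiguity policy: `N` never matches anything — it counts as a mismatch in
every comparison (even against another `N`) and never counts as G/C. This
is deliberately conservative for off-target counting; windows containing
`N` are enumerated but flagged (`has_ambiguity`) rather than dropped, so
the selection stage, not the enumerator, decides their fate.

The siRNA duplex model is a blunt 19-mer by default. An optional dTdT 3'
overhang can be rendered on both strands (`add_tt_overhang`); overhang
bases are presentation only and never enter search or annotation windows,
because overhang chemistry does not base-pair the target in the duplex
region that matters for specificity.

## Off-target search

Counting near-complementary genes is the specificity workhorse. The
engine is a pigeonhole seed-and-verify search (`build_index()`,
`search_index()`): each query is split into three segments; any occurrence
with at most two mismatches must contain at least one exactly matching
segment, so exact hash lookup of the three segments followed by full
Hamming verification is *complete* up to 2 mismatches — there are no
heuristic seed-region blind spots, and the test suite proves hit-set
equality against an independent exhaustive scan implemented as sparse
one-hot linear algebra.

Gene-level summaries (`summarize_hits()`) count **distinct genes** at
their *minimum* mismatch level (a gene with both a perfect and a 2-mismatch
hit counts once, at 0), and the intended target gene — identified by
`gene_id`, so splice variants are covered — never contributes. Counting at
the minimum level only is the order-free, non-double-counting reading of
"genes hit at 0, 1 and 2 mismatches".

Strand routing follows the biology of each modality. Databases are stored
as given (sense text) and searched in one canonical direction; the caller
supplies the query expected to occur verbatim in the text:

* **siRNA** — only the cDNA database is searched, once per strand. The
  guide base-pairs transcript text, so its target-matching query is the
  sense sequence (`cdna_mm0/1/2`); the passenger's is the antisense
  sequence (`cdna_pass_mm0/1/2`).
* **ASO** — the sense sequence is searched against both the cDNA and the
  unspliced-gene databases (`cdna_mm0/1/2`, `gene_mm0/1/2`); pre-mRNA
  matters because RNase H-dependent ASOs act in the nucleus.

Position-specific weighting of the siRNA seed region (guide positions
2–8) is intentionally **not** applied: all positions weigh equally in the
mismatch count, keeping the counts interpretable as plain alignment
results rather than a hybrid predictive score.

## Annotation

* `annotate_gc()` — GC percentage of the window.
* `annotate_snps()` — positional overlap with known SNPs
  (`start ≤ pos ≤ end`); allele-aware redesign is out of scope, matching
  the funnel's use of SNPs as a presence filter.
* `annotate_junction()` — a window spans an exon junction only when the
  junction offset is *strictly interior* to it: an oligo abutting a
  junction does not cross it. Junction-spanning oligos cannot match the
  unspliced pre-mRNA contiguously, which users may weight either way.
* `annotate_conservation()` — minimum Hamming distance of the sense window
  over all windows of each splice variant/ortholog, capped at 2 (`NA`
  beyond). Conservation is computed in target space (the sense window),
  and "conserved in species X" means some transcript of that species
  matches with 0 mismatches — the strictest reading, and the one that
  guarantees an identically matching ortholog site.

## Thermodynamics

Duplex stability uses the standard nearest-neighbor model: $\Delta G_{37}$
is an initiation term plus the sum of the $k-1$ dinucleotide stack
energies (plus terminal corrections where the parameter set defines them).
Two parameter sets ship as plain-text TSVs (columns `dimer`, `dH`, `dS`,
`dG37`; units kcal/mol and cal/(mol·K)): a unified **DNA:DNA** set with
terminal A·T/G·C corrections, and a **DNA:RNA hybrid** set keyed on the
DNA (oligo) strand, used for an unmodified DNA ASO bound to its RNA
target. Every loaded set is checked for internal consistency
($|\Delta G_{37} - (\Delta H - 310.15\,\Delta S/1000)| \le 0.05$ kcal/mol
per entry). The two-state melting temperature is

$$T_m = \frac{1000\,\Delta H}{\Delta S + R \ln(C_T/4)} - 273.15
  \; [+\; 16.6 \log_{10}(\mathrm{Na^+})],$$

with $R = 1.987$ cal/(mol·K), total strand concentration $C_T$ (default
1 µM) and the salt term applied when Na⁺ ≠ 1 M. These calculations assume
unmodified backbones; chemistries that raise $T_m$ substantially (LNA,
2'OMe) are deliberately not modeled — the notation layer records them, the
thermodynamics does not pretend to.

The intra/inter-molecular screens are simple, exhaustively checkable
surrogates rather than partition-function calculations:
`self_dimer_dg()` slides the oligo against a second copy of itself in
antiparallel register and scores every maximal run of ≥2 contiguous
complementary pairs as the nearest-neighbor energy of that run (so a
perfect palindrome scores exactly its full duplex energy), reporting the
most negative run or 0; `hairpin_screen()` finds the longest contiguous
inverted repeat with a loop of ≥3 nt, reporting 0 below a 4-bp stem.
Both are brute-force verified in the tests.

## Scoring

**siRNA** (`sirna_point_score()`): a fixed point-based checklist in the
Reynolds style, applied to the sense (passenger) strand of 19-mers, floor
0, maximum 10: +1 for GC in 30–52%; +1 per A/T at positions 15–19 (3'
sense end A/U-richness favors guide-strand loading); +1 when no 4-bp
hairpin stem exists; +1 for A19; +1 for A3; +1 for U10 (cleavage-site
preference); −1 for G/C at 19; −1 for G13. A machine-learned scorer can
replace it via the `efficacy_scorer` config key, which accepts any
function of the candidate table; the checklist is the shipped default
because it is transparent and needs no training data.

**ASO** (`aso_score()`): higher is better,
$$\mathrm{score} = S_\mathrm{affinity} - P_\mathrm{motif} - P_\mathrm{self},$$
where $S_\mathrm{affinity}$ rescales $-\Delta G_{37}$ linearly between
`a_min = 10` and `a_max = 25` kcal/mol and clamps to $[0,1]$ (weak target
binders score zero; the window brackets typical 20-mer DNA:RNA hybrid
energies); $P_\mathrm{motif}$ sums penalties of motifs matched in the
antisense compound (defaults: G₄ run 1.0 — the classic
toxicity/promiscuity liability — and A₄/T₄/C₄ runs 0.5 each);
$P_\mathrm{self}$ adds 0.5 each for a self-dimer stronger than −8 kcal/mol
and a hairpin stem of ≥6 bp. The constants are config-exposed defaults
chosen once as round, field-plausible values; they are stand-ins, not
fitted quantities.

`composite_score()` is the free-form weighted sum over any numeric
properties; a missing property is an error, never a silent zero.

## Selection

`apply_filters()` evaluates the hard filters in a fixed order — `snp`,
`motif`, `offtarget`, `conservation`, `score` — and records **every**
applicable rejection reason per candidate, so funnel accounting is exact
and reproducible. "Low complexity / promiscuous" is operationalized as
more perfect cDNA off-target genes than `max_perfect_offtargets` (default
0). Motif filters (default G₄ and T₄ runs) are applied to the antisense
sequence, i.e. the compound that will actually be synthesized.

`diversity_pick()` finalizes the panel by greedy max–min spread over start
positions: seed with the smallest start, repeatedly add the survivor
maximizing its minimum distance to the picks, ties to the smaller start.
Greedy max–min is a 2-approximation of the optimal spread; the test suite
checks that bound against exhaustive enumeration on a small instance. The
deterministic tie-break makes the whole funnel byte-reproducible.

## Notation

`modified_oligo()` holds an ordered 5'→3' monomer list over a closed
registry — sugars `dR` (DNA), `R` (RNA), `LR` (LNA), `mR` (2'OMe); bases
`A,C,G,T,U,5mC`; 3' linkers `P`/`sP` (phosphodiester/phosphorothioate),
with exactly the terminal monomer linker-free. `helm_write()` /
`helm_parse()` serialize to a HELM-style string
(`RNA1{[LR](G)[sP].[dR](A)P...}$$$$`) with a fuzz-tested round-trip
guarantee. Two text renderings substitute for GUI graphics:
`render_sequence()` (case encodes sugar, `+X` LNA, `mX` 2'OMe, `*` for
phosphorothioate) and `render_blocks()` (three fixed-width lines
emphasizing the modification pattern). `gapmer()` builds the classic
LNA-wing/DNA-gap/full-PS design directly. The registry is closed by
design; it covers every chemistry the renderings distinguish, and growing
it is a data edit, not a parser change.

## The synthetic workspace

`fixture_spec()` + `write_fixture_workspace()` generate a gene of random
exons and introns (defaults: 3 exons of 150–400 nt, introns 100–300 nt,
uniform base composition with a GC-bias knob), exon-skipping splice
variants, orthologs by i.i.d. per-base substitution (default mouse at 5%,
a realistic coding-sequence divergence scale), 10 random 1-kb decoy genes
with optional planted off-target windows at exact mismatch counts, and
SNPs whose reference allele matches the transcript. One master seed fans
out to per-component child seeds through a fixed hash, so adding a
component never perturbs another's stream, and two runs are
byte-identical.

What the generator does *not* emulate matters for interpreting green
tests: real transcripts have biased composition, repeats and paralog
families (harder off-target landscapes), empirical SNP spectra, and real
splice structures. Passing tests demonstrate algorithmic correctness —
exact search completeness, exact funnel accounting, exact thermodynamic
sums — not biological performance of the scoring defaults.

## Numerical and design choices

* Mismatch convention for ambiguity codes is not standardized; `N`-always-
  mismatches is this package's choice, made conservative on purpose.
* Off-target gene counts are per minimum mismatch level, not cumulative;
  cumulative counts are recoverable by summation.
* CSV export prints floating point at 4 decimals, flags as 0/1, missing
  as empty, LF endings, RFC 4180 quoting — a bit-exact surface for
  reproducibility checks (`write_candidates_csv()`).
* FASTA header fields are `|`-separated; gene defaults to the transcript
  ID and species to `"unknown"` when absent.
* Junction offsets from BED (0-based half-open) and GFF3 (1-based
  inclusive) normalize to identical 0-based junction positions; the two
  encodings of one structure are tested to agree.
* Exhaustive scans (hairpin, self-dimer) are $O(k^3)$/$O(k^2)$ on ≤25-mers
  — trivially fast at oligo scale and exactly testable, which is why they
  were preferred over heuristics.
* Problem sizes in the shipped tests (a 600-nt target against 50 one-kb
  decoys for search-equivalence, 1000-case oracle sweeps for
  thermodynamics, scoring and notation) were chosen as desk-scale
  workloads that still exercise every code path.

## Known limitations

The efficacy scores are transparent baselines, not trained predictors.
Thermodynamics ignores target secondary structure and modified
chemistries. The off-target search is exhaustive only to 2 mismatches and
ungapped — bulged or G:U-wobble off-targets are invisible to it. Selection
is single-objective filtering plus diversity; no Pareto treatment of
competing criteria is attempted.
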