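---
title: "Profiling carbohydrate-active enzymes, PULs and fermentation pathways in assembled metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling carbohydrate-active enzymes, PULs and fermentation pathways in assembled metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cazymer)
```

## Scope and data model

`cazymer` takes over where assembly, gene calling and homology search stop.
Its inputs are the post-assembly products a fiber-degrading-microbiome
study produces: contig FASTA (only headers and lengths matter), gene calls
in GFF3, HMM domain-hit tables in the per-domain tabular layout of
HMMER3's `domtblout`, per-protein similarity hits with taxonomic lineages,
bin membership and QC tables, and per-bin mapped-read counts. It does not
run Prodigal, HMMER or BLAST — their tabular outputs are the contract, so
the package stays light and fully testable offline.

All containers are plain data frames with fixed column names, and all
coordinates are 1-based inclusive (both genomic GFF3 coordinates and
protein alignment coordinates), matching the conventions of the formats
they come from. Malformed rows in large real-world tables are skipped and
counted (the count is attached to the returned table and announced in a
warning) rather than fatal; referential errors — a gene on an unknown
contig, a hit on an unknown protein — are fatal because silently dropping
them would bias every downstream census.

## The CAZyme annotation cascade

Candidate domains arrive as raw `hmmscan`-style hits. Three stages turn
them into per-protein annotations:

1. **Filtering** (`filter_hits`). A hit survives iff its HMM model
   coverage is at least 30% *and* its e-value passes the regime matching
   its alignment length: alignments longer than 80 residues need
   e ≤ 1e−5, alignments of at most 80 residues need e ≤ 1e−3. "Longer
   than" is read strictly: an 80-residue alignment is judged in the
   lenient short regime, an 81-residue one in the strict regime. Coverage
   is model (HMM) coverage, the dbCAN convention; all four thresholds are
   arguments.
2. **Overlap resolution** (`resolve_overlaps`). Per protein, hits are
   ranked by e-value (ties: higher bit score, then family id) and
   accepted greedily; a hit is dropped iff its alignment interval shares
   at least one residue with an already accepted hit. This is interval-
   based rather than keep-one-per-protein because multi-domain CAZymes
   (a GH plus its CBM, tandem cohesins) are real and must survive; only
   genuinely competing placements are resolved.
3. **Classification** (`classify_cazymes`). Each protein's *primary
   class* is the class of its best (lowest-e-value) retained hit, with a
   fixed tie order GH < PL < CE < CBM < GT < AA < cellulosome < SLH <
   Sus. A single primary class per protein makes class fractions sum to
   100% over CAZyme proteins; the complete multi-domain inventory is
   retained alongside (`families`, `is_multidomain`), and family-level
   tables count distinct protein–family pairs, the per-sequence-per-family
   convention used in CAZyme census tables.

Glycoside hydrolases are then grouped by substrate
(`substrate_categories()`): cellulases (GH5, GH9, GH44, GH45, GH48,
GH74), endohemicellulases (GH8, GH10, GH11, GH12, GH26, GH28, GH53),
debranching enzymes (GH51, GH54, GH67, GH78) and oligosaccharide
degraders (GH1, GH2, GH3, GH29, GH35, GH38, GH39, GH42, GH43, GH94). The
map is user-overridable and validated (pairwise disjoint, GH-only).
Published family lists for the oligosaccharide group vary between GH9 and
GH94 in otherwise identical enumerations; the default here uses GH94 plus
GH1, which keeps the categories disjoint (GH9 is a cellulase family).

Cellulosome potential is screened two ways (`call_scaffoldins`): a
template-score cutoff of 700 on supplied iterative-search scores against
canonical scaffoldins (CipA/ScaB/CbpA-type templates), inclusive at the
threshold, and a structural mode flagging any protein with two or more
cohesin domains. Tandem cohesins are counted without a spacing rule —
any multiplicity of cohesin hits on one protein qualifies, since
published descriptions give no inter-domain distance constraint.

## Census metrics

`cazyme_census` reports the quantities used for cross-metagenome
comparison: counts per class and family, GH density per Mbp of assembled
DNA, CAZyme and GH fractions of the ORF universe, full-length-gene
fraction. Densities and percentages display at one decimal but are stored
unrounded; the ORF denominator in use is named in the output, because
comparison tables in the literature are ambiguous about whether the
denominator is all ORFs or ORFs on ≥ 1 kb contigs. A `min_contig_bp`
argument reproduces the ≥ 1 kb restriction used in such comparisons.

## Enrichment statistics

`compare_profiles` tests each family's count in metagenome A against
metagenome B with a two-sided Fisher's exact test on
`[[count, total − count]]` rows, adjusts p-values with Benjamini–Hochberg
(the standard reading of an unqualified "FDR correction"), and assigns
tiers (`***` q < 0.001, `**` q < 0.01, `*` q < 0.05). The margins are the
caller's choice — total predicted ORFs by default, or total CAZyme genes —
because published comparisons do not state them; the totals are echoed in
every output row so the choice is always visible. The reported odds ratio
is the sample odds ratio (0/0 → 1, x/0 → ∞), not the conditional-MLE
estimate `fisher.test` prints, since the sample version is what the 2×2
construction defines.

Calibration is checked, not assumed: the test suite draws 200 pairs of
profiles from one shared multinomial (`null_profile_pair`) and verifies
the fraction of families reaching q < 0.05 stays within three standard
errors of the nominal rate.

## PUL detection

A polysaccharide utilization locus is anchored on a tandem SusC–SusD gene
pair. `find_sus_pairs` scans each contig's gene order for a
SusC-annotated gene and a SusD-annotated gene (SusD-like variants count
as SusD) separated by at most `max_pair_gap_genes` intervening genes
(default 0, strictly tandem), in either order, greedily left-to-right
with each gene in at most one pair. Strand is ignored for pairing and
extension but reported per member, as no strand rule is part of the
published locus definition.

`extend_pul` grows the locus outward: a gene joins if it is
CAZyme-annotated (GH/CE/PL/CBM/Sus), together with any interior genes it
skips over (kept and counted as unknown-function members); extension
stops in a direction after `window_genes` (default 5) consecutive
non-CAZyme genes. The window default reflects typical PUL gene density
and is a flag precisely because locus counts depend on it. Loci whose
member ranks come within `merge_gap_genes` (default 2) of each other
merge, so arrangements like susC-susD-susC-susD-susE with interleaved
degradative genes are reported as one locus with two Sus pairs;
`merge = FALSE` switches to pair-level counting. Both parameters are
provably monotone (window up ⇒ members never shrink; merge gap up ⇒
locus count never grows), and the suite asserts this.

## Bin profiling and pathway screening

`qc_gate` retains bins strictly above 50% completeness and strictly below
10% contamination by default; the thresholds are arguments because
published bin sets are sometimes reported at a stricter (> 70%)
completeness cut. `bin_abundance` offers the mapped-read fraction (`raw`)
and a size-normalized variant (`per_bp`) that scales each bin's read
fraction by mean-bin-size/bin-size; the absolute scale of size-normalized
abundance is conventional, so it should be read as a relative measure.

VFA capability calls are marker-gene presence logic over annotation
symbols: acetate needs `ackA` *and* `pta`; propionate via succinate needs
`mmdA`, via acrylate `lcdA`, via propanediol `pduP` or `pduQ`; butyrate
via butyrate kinase needs `buk`, via butyryl-CoA:acetate CoA-transferase
`but`. Symbols are matched as whole lowercase tokens — never substrings,
which matters because `but` is an English word. The screen consumes
annotations supplied in the GFF (`gene=` attributes); it performs no
homology search of its own, so its sensitivity is exactly that of the
upstream annotator.

## LCA taxonomy

`lca` mirrors the MEGAN-style assignment: among a protein's similarity
hits (pre-screened at e ≤ 1e−3, at most 20 per protein), keep those
within `top_percent` (default 10%) of the best bit score, then assign the
deepest rank at which all retained lineages agree. The exact
parameterization of published MEGAN runs is rarely stated, so the window
is a flag, and `top_percent = 100` gives the pure LCA over all retained
hits. Raising the window can only widen the retained set, hence never
deepen an assignment — a property the suite checks. Lineages travel
inside the hit table as `rank:name` strings; no taxonomy database is
downloaded.

## The synthetic community

`simulate_metagenome` builds a seeded community with planted ground
truth. The default configuration emulates the structure of a
fiber-adherent rumen community at desk scale: six bins — three
Bacteroidetes-like (oligosaccharide-degrader-rich GH2/GH3/GH43 profiles,
two planted PULs per bin including a two-pair
susC-susD-susC-susD-susE + GH10/GH43/GH67/GH5/CE6 arrangement, `but`
butyrate route), two Firmicutes-like (GH5/GH9/GH13-rich, dockerin and
tandem-cohesin proteins, `buk` route) and one Fibrobacteres-like
(cellulases and hemicellulases, no debranching enzymes, no
dockerin/cohesin) — with 3–4 contigs per bin and 40–55 genes per contig.
Planted loci are separated from other CAZymes by 8 plain genes, beyond
the default extension window, so recovery must be exact, not approximate.

True domain hits always pass the filtering cascade (e-values 1e−10 to
1e−25, coverage ≥ 0.5, alignments capped at the planted domain block so
they never overlap). Decoy hits are added per protein at `noise_rate`;
by default every decoy is drawn with model coverage below 0.30, so it is
rejected by construction and the planted census is recovered exactly —
`noise_pass_fraction` lets a configured share of decoys pass instead,
which corrupts annotations deliberately for robustness experiments.
Protein and contig residues are random placeholders: no pipeline stage
reads sequence content, so no biological realism in residues is
attempted. All randomness flows from one seed; identical seeds reproduce
the emitted files byte-for-byte.

What passing on this generator does *not* show: performance on real
assemblies with fragmented genes, chimeric contigs, shared marker genes
between bins, or HMM hits whose scores sit near the thresholds.
The generator plants clean signal and clean noise; it validates the
logic, not the upstream annotation quality.

## Problem sizes and numerical choices

The test suite runs the full pipeline on 20 seeds of the default
six-bin community (~1,100 genes each), 200 null profile pairs of 40
families at depth 2,000 for FDR calibration, exhaustive 2^8 marker truth
tables, and 100–200 random small lineage fixtures (≤ 6 leaves) for the
LCA oracle. Fisher p-values are compared with a brute-force
hypergeometric enumeration at tolerance 1e−10; BH q-vectors with the
literal step-up formula at 1e−12. Tie-breaks everywhere are total and
deterministic (documented sort keys), so repeated runs and row
permutations give identical outputs; the suite asserts permutation
invariance and idempotence of the filter and overlap-resolution steps.

## Known limitations

* Marker-gene and scaffoldin evidence are consumed, not computed; the
  package inherits upstream annotation errors.
* The Fisher margins and the abundance normalization each have two
  defensible conventions; both are surfaced as options rather than
  decided silently, and outputs echo the convention used.
* PUL substrate specificity and regulatory-gene content are out of
  scope; `gene_symbols` pass through for downstream inspection.
* The LCA implementation assumes consistent lineages in the hit table;
  it does not reconcile conflicting rank orders across databases.
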