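---
title: "Methods: genome-wide assessment of a CRISPR-edited diploid strain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide assessment of a CRISPR-edited diploid strain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

crisprStrainScan asks a single question of a CRISPR/Cas9-edited diploid
microbial strain and its parental wild type: beyond the intended edit,
what changed? It answers it from variant-level inputs — a reference
genome, per-strain genotyped variant calls, window coverage tracks and
structural-variant (SV) call tables — rather than from reads. Read
processing (trimming, alignment, calling) is upstream of this package;
the pipeline consumes the standard output formats of that tooling, or
the equivalents produced by its own simulator.

The motivating setting is a diatom (*Phaeodactylum tricornutum*-like)
strain pair: a highly heterozygous diploid (about 0.98% of positions
heterozygous genome-wide) carrying a biallelic heterozygous knockout — a
1-bp deletion four bases 5' of the PAM on one allele and a multi-kb
deletion on the other — where the questions of interest are off-target
mutations, long tracts of loss of heterozygosity (LOH), and
strain-specific structural variation.

# Guide checks and off-target search

A guide is a 20-nt protospacer plus a PAM pattern (NGG for SpCas9, which
cleaves 3 nt upstream of the PAM). Two design heuristics are reported:
GC content (guides above 70% GC are associated with elevated off-target
activity) and the seed region, the 8–12 PAM-proximal bases whose
mismatches most strongly abolish cleavage. The seed length defaults to
12, the conservative upper end of that range.

`findOffTargets()` is an exhaustive PAM-constrained scan: every 20-nt
window on either strand whose adjacent 3' trinucleotide matches the PAM
and whose Hamming distance to the protospacer is at most
`maxMismatches` is reported, with total and seed mismatch counts. The
contract is equality with a naive position-by-position comparison — the
test suite enforces this against an independently written scanner — and
the implementation is free to generate candidates efficiently (it uses
`Biostrings::matchPattern` and then applies the PAM filter). Windows
containing N are skipped rather than guessed at. `maxMismatches`
defaults to 4, a conventional setting for Cas9 off-target screens at
small genome sizes; the published screens this mirrors do not state
their setting, so the default is configurable and no claim of count
parity with any specific tool is made. Bulges (insertion/deletion
alignments of the guide) and activity score models (MIT/CFD) are out of
scope.

`scoreGuide()` aggregates the scan into a design report, excluding the
single designated on-target site (the first 0-mismatch hit); if no
0-mismatch site exists, a warning is raised and every site counts as an
off-target.

# Variant filtering and strain comparison

Variant records carry chromosome, 1-based position, ref/alt alleles,
quality, genotype (0/0, 0/1, 1/1 or missing) and depth. Multi-allelic
VCF rows are split into one record per alternate allele, re-expressed as
that allele's dosage. Filtering keeps records with quality strictly
above 30 (a record at exactly 30 is removed) and depth within [5, 200].
The upstream caller's mapping/base-quality options act at the read level
and are not re-applied here.

Two strains are compared by exact (chromosome, position, ref, alt)
identity — no fuzzy matching, because both strains are expected to come
from one caller run and normalized representations. A variant seen in
only one strain is *strain-specific* only when the other strain has
depth ≥ 5 at that position in its coverage track; otherwise it is
*dropped* as unresolvable. This deterministic coverage rule replaces
manual curation of candidate differences: "absence of the call" is only
evidence when the position was sequenced. The three reported sets
(shared, WT-only, MUT-only) plus the dropped set always partition the
union of the filtered inputs.

Strain-specific variants are intersected with predicted off-target
sites over a flanked window (default ±20 bp around the 20-nt site,
half-open). An empty intersection is the desired negative result: no
specific SNP or indel at any predicted off-target.

# Windowed heterozygosity and LOH calling

Each chromosome is tiled with half-open 50 kb windows (the last window
truncated) and per-window heterozygous (0/1) and homozygous (0/0, 1/1)
genotyped variants are counted. Two heterozygosity definitions coexist
because both are in common use: per-variant (percentage of heterozygous
calls among genotyped variants in the window; undefined and flagged
when the window has none) and per-bp (heterozygous sites over window
length, as a percentage; always defined). Both are emitted. Profile
smoothing is loess — per-chromosome tricube-weighted local linear
regression (`stats::loess`, degree 1) on window midpoints, with
undefined windows interpolated from the fit — and is display-only: it
never feeds segment calling. Spans are widened automatically on very
short profiles so the local fit retains enough points; chromosomes with
fewer than three defined windows are returned unsmoothed with a
warning.

Differential LOH calling compares the two strains in both directions.
Window flagging (affected strain ≤ 0.2% per-bp heterozygosity while the
other strain ≥ 0.5%, runs merged across ≤ 1 unflagged window) detects
multi-window tracts; the thresholds are not taken from any publication
but chosen so that the contrast observed in real affected regions
(0.04–0.09% against chromosome backgrounds of 1.1–1.3%) is separated by
more than five-fold, and they are configurable. Window flagging cannot,
however, resolve a tract smaller than one window: a 20 kb tract inside
a 50 kb window leaves the window's heterozygosity far above any
sensible threshold. Since the smallest LOH events worth reporting are
of exactly that size, a second, variant-level detector runs alongside:

* *Informative sites* are positions heterozygous in the unaffected
  strain. A site is *discordant* when the affected strain is homozygous
  or absent there.
* Maximal runs of discordant sites are formed, tolerating up to 3
  intervening concordant sites — the tolerance accommodates residual
  heterozygosity inside real gene-conversion tracts (observed affected
  regions retain ~6% of their heterozygous sites). Runs with ≥ 20
  discordant sites become candidates; at a 0.98% background the chance
  of such a run arising from strain-specific variation alone
  (per-site discordance ~4%) is negligible.
* A run's reported boundaries are the midpoints between its outermost
  discordant sites and the flanking concordant informative sites: the
  true breakpoint is equally likely anywhere in that flanking gap, so
  the midpoint is the unbiased estimate with expected error of half the
  inter-variant spacing (~50 bp at this density).
* Window-level candidates are refined to their overlapping runs;
  all candidates are merged when closer than 2 kb; a candidate is
  discarded only when even its *maximal consistent extent* — up to, but
  excluding, the flanking concordant sites — falls below the 20 kb
  minimum segment length. Discarding on the (inner or midpoint)
  refined length instead would systematically reject true tracts at
  exactly the minimum size, because refinement is always clipped inward
  by about one inter-variant spacing per side.
* Kept segments must still show the heterozygosity contrast over their
  refined interval, which guarantees `hzAffected < hzOther` on every
  reported segment.

Mechanism classification uses depth only: a hemizygous deletion halves
the mapped-read depth over the lost interval, gene conversion leaves it
unchanged. The segment's mean depth in the affected strain over its
genome-wide median depth classifies it as deletion (ratio ≤ 0.6), gene
conversion (ratio in [0.8, 1.2]) or ambiguous (anything else, including
missing coverage). The bands deliberately do not touch so that borderline
ratios are surfaced rather than forced.

HMM segmentation, B-allele-frequency methods and phasing are out of
scope; the run-based detector with the gap tolerance above is this
package's answer to sub-window LOH resolution.

# Strain similarity

Genotypes are encoded as alternate-allele dosage (0/0 → 0, 0/1 → 1,
1/1 → 2) over the union of variant keys; dosage is the standard scalar
encoding and makes Euclidean distance an allele-sharing metric. A key
absent from one strain's calls is homozygous reference (0) when that
strain is covered there, missing otherwise; statistics use
pairwise-complete sites. Pearson correlation is undefined on
zero-variance columns and flagged rather than propagated as NaN. Allele
frequencies default to dosage/2 when per-allele depths are unavailable.
The all-pairs table mirrors the conventional mixed-triangle layout
(correlations below the diagonal, distances above).

# Structural variants

SV tables are BEDPE-like TSVs with four classes: DEL, INV, ITX
(intra-chromosomal translocation) and CTX (inter-chromosomal
translocation). Intra-chromosomal sizes are end − start (half-open);
CTX records have no size and are excluded from mean-size summaries.
Support filtering keeps records with at least 10 supporting reads
(inclusive). Cross-strain matching requires the same class, both
breakpoints within 1 kb, and — for intra-chromosomal classes — reciprocal
overlap ≥ 0.5, assigned greedily by total breakpoint distance with each
record used at most once; these programmatic defaults replace manual
curation of strain differences. Deletions can additionally be tested
against the coverage track: mean depth over the interval relative to the
genome median at or below 0.6 supports a hemizygous deletion, at or
below 0.1 a homozygous one.

# The simulator

`simulateReference()`/`simulateStrainPair()` generate the study
conditions every stage is scored against, with a machine-readable truth
table. Defaults are the conditions of the motivating study where stated,
and field-typical values elsewhere:

* shared heterozygous SNP background at 0.0098 per bp (0.98%), genotype
  0/1 in both strains;
* strain-specific small variants at 4e-4 per bp per strain (the scale
  implied by roughly 12,000 specific variants on a 27 Mb genome), 81%
  SNPs and 19% 1-bp indels;
* the biallelic target edit: a 1-bp deletion at PAM position −4
  (genotype 0/1, left-anchored VCF representation) in the mutant only,
  and a 3,639 bp deletion on the other allele starting 12 bp 5' of the
  deleted base, emitted as a DEL SV record with halved coverage; shared
  heterozygous sites inside it are forced homozygous (hemizygosity);
* LOH tracts per specification, gene conversion (no depth change) or
  hemizygous deletion (depth halved), with residual heterozygosity
  defaulting to 6e-4 per bp (~0.06%, the level seen in real affected
  regions);
* off-target decoys built by mutating the protospacer at exactly the
  requested total and seed mismatch counts, planted with intact PAMs;
  after planting, the genome is re-scanned and re-drawn if the random
  background produced any accidental near-match, so the truth table is
  exact by construction;
* coverage at window resolution: independent Poisson draws around the
  configured mean (default 100), windows split at the boundaries of
  depth-halving features. Read-level simulation is deliberately absent —
  every downstream consumer reads depth ratios, not reads.

Coordinates are 0-based half-open internally, with interval length
end − start; VCF output is 1-based per the standard. All randomness
flows from one configured seed, and a fixed seed reproduces every
output file byte for byte.

What the simulator does *not* emulate bounds what passing tests show
about real data: no sequencing error or miscalled genotypes outside LOH
tracts, no mapping artefacts or coverage waves, no mosaicism within a
colony, no multi-allelic sites, and variant positions are uniform
rather than clustered. Detection thresholds tuned here should therefore
be revisited on real call sets, where quality and depth filters do real
work; the simulator's variants all pass the default filters by
construction, which is intended — it isolates the comparison logic from
the filtering logic, which is tested separately on hand-built records.
One further simplification: strain-specific *small* variants inside
planted deletion tracts are not forced homozygous, which slightly
understates hemizygosity there; segment calling is driven by the shared
background, so this does not affect the reported results.

# Problem sizes and runtime choices

The test suite and the acceptance script run simulations of one or two
chromosomes of 0.12–1 Mb — large enough that a 1 Mb chromosome carries
~9,800 heterozygous sites and a 20 kb tract ~200 informative sites, so
recovery statistics are meaningful, while a full run of the suite stays
in the tens of seconds. Oracle-equivalence checks for the off-target
scan use 15–30 kb genomes with planted mismatch ladders, the scale at
which an intentionally naive position-by-position scanner is still
comfortable. Planted-LOH precision/recall is measured over 20 seeded
replicates with tracts of 30, 50 and 80 kb.

# Known limitations

* LOH boundary precision is limited to the inter-variant spacing; at
  0.98% heterozygosity this is ~100 bp, and a residual heterozygous
  site surviving near a tract edge can clip the detected extent by a
  few hundred bp — occasionally below the minimum length for tracts at
  exactly 20 kb.
* The variant matcher is exact-key; call sets from different callers or
  unnormalized VCFs must be left-aligned/normalized upstream.
* Mechanism classification assumes diploidy and a single copy-number
  change; nested or homozygous events outside the two bands are
  reported as ambiguous, not resolved.
* The off-target scan models substitutions only (no bulges) and treats
  all mismatches equally apart from the seed/non-seed split.
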