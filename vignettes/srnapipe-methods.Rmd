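---
title: "srnapipe: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{srnapipe: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`srnapipe` analyses two-condition small RNA sequencing experiments — the
running example throughout is a sulfur-replete (+S, control) versus
sulfur-deprived (−S, treatment) contrast in *Chlamydomonas reinhardtii* —
from raw reads to a differential expression table. This vignette records
the models the package implements, the parameters that matter, and the
decisions taken where the design was genuinely open.

## Read cleaning

Raw reads pass a seven-step elimination cascade: (1) low quality,
(2) 5′-adapter contamination, (3) missing 3′ adapter, (4) empty insert,
(5) poly-A insert, (6) insert shorter than 18 nt; survivors are collapsed
into unique tags (step 7 summarises their length distribution). Each
read is charged to the *first* filter it fails. This first-failure-wins
attribution is a design choice: published library-statistics tables list
the categories but not how a read failing several filters is counted,
and first-match accounting is the only convention under which the
categories provably sum to the high-quality total. The package asserts
that conservation identity on every run. (One published table in this
domain prints a −S clean-read count one read above its category sum;
`cleaning_report()` treats such input as an accounting error rather than
reproducing it.)

Parameters, with defaults:

* `quality_threshold = 20` (Phred), `max_low_quality_frac = 0.5` — a read
  is low quality when more than half its calls fall below Q20. The
  upstream instrument filter separating "total" from "high-quality"
  reads is never specified in the reports this mirrors, so the criterion
  is parameterised and this default documented as an assumption.
* `min_adapter_match = 6` — the 3′ adapter is located by the leftmost
  exact occurrence of its leading 6-mer. Exact seeding keeps the stage
  deterministic; mismatch-tolerant trimming is deliberately out of scope.
* `polyA_frac = 0.8` — an insert is poly-A when ≥80% of its bases are A;
  the threshold is a package definition (none is published) and is
  configurable.
* Inserts longer than 30 nt are *not* truncated: they are counted in
  their own report field (`over_30nt`) and excluded, since clean tags
  are defined as 18–30 nt and silent truncation would fabricate tags.

Tags are stored in the DNA alphabet internally and rendered as RNA (U)
in miRNA-facing reports.

## Exact mapping

Tags map to the genome with zero mismatches on both strands, all loci
reported. The index hashes every plus-strand k-mer (k = 18, the minimum
tag length); a minus-strand hit is a plus-strand occurrence of the
tag's reverse complement, so one single-strand index serves both.
Minus-strand hits are stored in plus-strand coordinates (start < end)
with a strand flag. The mapper is deliberately simple enough to verify:
the test suite checks it hit-for-hit against a naive sliding-window scan
(through `Biostrings::matchPattern`) on kilobase-to-100 kb genomes.
Multi-locus tags are fully reported here; the copy-number cap applies
downstream in prediction, so annotation sees every locus.

## Annotation priority

Every unique tag receives exactly one category:
structural RNA (rRNA, scRNA, snRNA, snoRNA, tRNA; Genbank tier beats
Rfam tier) > known miRNA > repeat > exon > intron, with `unann` for tags
matching nothing. Choices worth recording:

* A hit counts only when *fully contained* in an annotation interval.
  Partial-overlap handling is unspecified in the method this mirrors;
  containment is the stricter, deterministic reading and is configurable
  at the database level by widening intervals.
* Exon/intron assignments record sense/antisense from strand agreement,
  mirroring the standard composition tables.
* mRNA-fragment annotation ("degraded fragments of mRNA") is interval
  overlap of genomic hits rather than alignment to spliced transcripts —
  equivalent for exact matches and far simpler to test.
* Within one structural tier, ties across categories break in a fixed
  order (rRNA, scRNA, snRNA, snoRNA, tRNA) so results are independent of
  hit order; a property test shuffles hits to confirm.
* The BLAST-based matching (E ≤ 0.01) used with live Genbank/Rfam cannot
  be reproduced offline; exact interval matching against provided
  annotation stands in, and the tiers come from the GFF3 source column.
* siRNA is a reported category but is assigned *after* priority
  annotation, claiming only tags that were `unann` or exon/intron
  fragments. Where siRNA sits in the priority chain is unstated in the
  original rule; claiming only leftovers keeps structural RNA and known
  miRNA assignments stable.

## siRNA duplexes

A duplex is two 22–24 nt tags on opposite strands whose spans satisfy
the 2-nt 3′-overhang geometry; in plus-strand coordinates the minus span
equals the plus span shifted by −2, which forces equal strand lengths.
The criterion is evaluated in genome-coordinate space — for exact-match
tags this is equivalent to aligning tags to each other, and it is the
implementable reading of the published structural description (the
original used an unavailable in-house tool). The 22–24 nt range comes
from the defining sentence; a background remark that "siRNA is 24 nt" is
treated as descriptive, not as a filter. Pairs are deduplicated by
locus, and a tag may participate at several repeated loci.

## RNA folding

The default folding engine is a minimum-energy nested-structure dynamic
programme with pair energies GC −3.0, AU −2.0, GU −1.0 kcal/mol and a
minimum hairpin loop of 3 nt. Ties break deterministically: pairing the
5′-most open position beats leaving it unpaired, and among equal-energy
partners the 3′-most partner wins — the latter keeps helices contiguous
in stem-loops instead of pairing into the hairpin loop, which matters
for duplex statistics. The engine is intentionally simple so that it can
be verified exhaustively: tests compare its minimum energy against
brute-force enumeration of all nested structures for hundreds of
sequences up to 20 nt, and re-score every returned structure
independently. A thermodynamic nearest-neighbour engine (ViennaRNA's
`RNAfold`) can be plugged in behind the same contract
(`fold(engine = "vienna")`), but its kcal/mol scale differs from the
simple model's, so published precursor MFE values from thermodynamic
folders are *not* reproduction targets for the default engine.

## Novel miRNA prediction

Unannotated tags of mature length (18–25 nt) with at least `min_reads`
(default 2) supporting reads and at most 20 genomic loci are candidate
matures. Around each locus the package excises windows treating the tag
as the 5′ or the 3′ precursor arm, with 20 nt of flank and up to 300 nt
of miRNA–star space — scanning a ladder of extents (40, 70, 110, 160,
220, 300 nt) because short precursors are found reliably in short
windows whose fold is not confounded by flanking sequence. Each window
is folded; the star arm is located as the contiguous region pairing with
the mature (majority side; partner clusters split where a gap would
imply a bulge beyond the bulge bound; the star is offset so each duplex
strand carries a 2-nt 3′ overhang). The stem-loop core spanning mature
and star is then excised and refolded, and the candidate's statistics
and MFE are taken from that core fold — flanking sequence competes with
the star for mature pairing and would otherwise corrupt the duplex
statistics; the reported precursor interval extends the core by the
20-nt flank. A candidate is accepted iff

* precursor MFE ≤ −18 kcal/mol,
* ≥ 16 paired mature positions in the miRNA/miRNA\* duplex,
* longest one-strand bulge ≤ 4 nt,
* duplex asymmetry ≤ 4 nt,
* mature and star on opposite arms of one stem-loop,
* miRNA–star spacing ≤ 300 nt.

All thresholds are inclusive (an MFE of exactly −18 and a duplex of
exactly 16 pairs are accepted). Per tag, the best accepted candidate is
kept: lowest MFE, then shortest precursor, then leftmost coordinate. The
"reference sequence length 20/23" parameters familiar from Mireap-style
configurations have no published definition; they are interpreted as the
expected star length, recorded on each candidate (`star_length`) but not
enforced as an acceptance filter, since the duplex criteria above
already constrain the star. Star-strand expression evidence is likewise
not required. Known miRNAs are quantified separately by exact identity
with a mature sequence or exact containment in a precursor; a tag
matching several known miRNAs is counted for each and flagged.

## Differential expression

Counts are normalised to tags per million, `TPM = count / total × 10⁶`,
with the library's clean-read total as denominator. The fold change is
`log2(treatment / control)` on TPMs. Significance uses the
Audic–Claverie conditional test on *raw* counts: given `x` reads among
`N1` in the control library, the treatment count `y` among `N2` follows

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
\frac{(x+y)!}{x!\,y!}
\left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)},$$

a negative binomial with size `x+1` and success probability
`N2/(N1+N2)`. Numerical choices: everything runs in log space via
log-gamma, so counts to 10⁷ and totals to 10⁸ cannot overflow; the upper
tail is summed in blocks past the distribution mode until the remaining
terms are negligible (relative cutoff 10⁻¹⁵); tests verify normalisation
to 1 ± 10⁻⁹, the equal-totals closed form
`C(x+y, y)·2^−(x+y+1)`, and agreement with `pnbinom` tails to 10⁻¹⁰.

The reported p-value **conditions on the treatment count and doubles
the tail of the control count in the direction of observed change**:
`p = 2·C(x′ ≤ x | y)` for up-regulation, `2·D(x′ ≥ x | y)` for down,
capped at 1. Published presentations of this test print the conditional
distribution and both cumulative tails without stating how they
combine; the convention here was identified by inversion — for
published rows whose normalized values recover integer counts, it
reproduces the printed p-values to at least eight significant digits
(e.g. counts 28/68 with
library totals 10 029 992 / 9 918 931 give 3.00277572489945 × 10⁻⁵),
and as a genuinely two-sided test it holds the simulated type-I rate at
the nominal level, which a single tail chosen post hoc would not.
Labels: `**` for p < 0.01, `*` for 0.01 ≤ p < 0.05, boundaries
exclusive.

Zero counts receive no pseudocount: a miRNA seen in only one library
becomes a condition-specific call (`plus_only`/`minus_only`) with no
fold change, and enters the significant set when its nonzero count
reaches `specific_floor` (default 10) reads. "Fold change > 2" screens
are implemented as |log2 FC| ≥ 1 with p < 0.05. No multiple-testing
correction is applied, matching the practice of the reports this
format mirrors; for modern reanalyses an FDR step would be the first
addition.

## Synthetic data: what it emulates and what it does not

The generator plants ground-truthed features in a random-background
genome (default GC 0.6, matching a GC-rich algal genome): miRNA hairpins
built as `mature + loop + star` with the canonical 2-nt 3′-overhang
duplex, siRNA duplex loci, structural RNA genes, an exon, an intron and
a repeat. Reads are feature tags plus 3′ adapter, padded to 36 nt, with
contaminant classes generated per category at exact per-class counts
(`round(fraction × total)`), so the cleaning report can be checked
against the truth exactly; per-feature counts are multinomial with
expectation `TPM × total / 10⁶`; library totals are exact by
construction. Fixed seeds reproduce files byte for byte.

The bundled demo (`demo_simulation()`) uses three chromosomes of
60/40/30 kb, twelve 21-nt hairpins (six induced four-fold under −S,
three unchanged, three −S-specific — echoing the fold-change and
condition-specificity patterns of published sulfur-deprivation tables;
abundances are set so every expressed hairpin receives ≥ ~50 reads at
the default 50 000-read libraries), five siRNA loci and seven structural
RNA/mRNA features, with ~8.7% contaminant reads across all classes. The
mature sampler rejects candidates whose constructed precursor does not
itself pass the hairpin criteria — a planted miRNA must *be* a miRNA
under the package's energy model, otherwise recovery would measure the
generator, not the pipeline.

What the generator does **not** emulate: sequencing errors, quality
score realism, instrument artifacts, isomiR heterogeneity around mature
ends, RNA editing, or a realistic repeat landscape. Passing the
recovery tests therefore shows the pipeline's logic is correct on clean
data; it does not show robustness to error-rich real libraries. One
realistic artifact the random background *does* produce is genuine but
unplanted structure: random GC-rich sequence contains loci that
legitimately satisfy the hairpin criteria, and independently sampled
background fragments occasionally satisfy the duplex geometry, so novel
candidate and siRNA pair lists are supersets of the planted truth.
Recovery metrics (`compare_truth()`) measure the planted features found,
not the absence of such extras.

## Problem sizes and determinism

The shipped tests run the full pipeline on 2 × 12 000-read libraries
over a 130 kb genome (about a minute), verify folding against
enumeration at ≤ 20 nt, mapping against a naive scan at 100 kb, test
calibration with 1000–2000 simulated count pairs, and determinism by
byte-comparing the outputs of two runs under one configuration. The
analysis itself contains no randomness; only the simulator consumes the
seed.

## Known limitations

* The default energy model ignores stacking, dangles and loop entropies;
  its MFE values are comparable only within the model. Use the ViennaRNA
  engine for thermodynamically meaningful energies (with a recalibrated
  MFE threshold).
* Exact matching throughout (mapping, known-miRNA quantification,
  adapter seeds) makes the pipeline conservative on error-containing
  reads; counts are undercounts in the presence of sequencing error.
* The annotation stage emulates database tiers from provided files; it
  does not perform homology search.
* The Audic–Claverie test models sampling noise only; with biological
  replicates a dispersion-aware model (e.g. a negative binomial GLM)
  should replace it.
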