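---
title: "Detecting and quantifying internal tandem duplications: methods"
author: "itdseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying internal tandem duplications: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itdseq)
```

## The problem

Internal tandem duplications (ITDs) are in-frame duplications of a gene
segment inserted adjacent to the template copy.  They are notoriously easy
for standard short-read pipelines to miss: reads crossing the duplication
junction do not match the reference collinearly, so mappers either
soft-clip them or discard them as discordant mate pairs, and a naive
variant caller sees at most a cryptic substitution near the breakpoint.
The motivating case is the X-linked BCL-6 co-repressor gene *BCOR* in
clear cell sarcoma of the kidney, where recurrent 87–114 bp in-frame ITDs
cluster in the terminal coding exon and target the C-terminal PUFD domain
(amino acids 1,701–1,755), sometimes interrupted by a short non-templated
junctional insertion.  Because the gene is X-linked, a male (hemizygous)
tumour can carry the ITD on every expressed copy, so mutant transcripts
can account for essentially all locus expression.

`itdseq` re-implements the computational skeleton of that discovery as a
tested, reusable pipeline at desk scale: a coordinate model for a
minus-strand locus, a paired-end read simulator with ground truth, a
soft-clipping semi-global aligner, a clip-harvesting ITD detector with
discordant mate-pair corroboration, an HGVS-style annotator, the
tumour/normal somatic filter, a two-reference expectation-maximization
(EM) quantifier of mutant vs wild-type expression, and the
FPKM/Spearman/UPGMA expression recipe.

## Coordinate model

A `locus_model` ties exon intervals on a contig to the spliced transcript
sequence and the CDS geometry.  Coordinates are 1-based inclusive
everywhere; half-open forms appear only at serialization boundaries.  On
the minus strand the genomic-to-coding map is per-exon affine with slope
−1 (`c = A − (g − g0)` for an exon anchor pair `(g0, A)`), so a single
anchor pair fixes the whole exon.  Multi-exon transcripts are supported;
the bundled BCOR-like fixture keeps the entire ITD region inside its
terminal exon, as in the real locus.

The packaged fixture (`synthetic_bcor_locus()`) is a *synthetic*
stand-in: the true mRNA sequence is not redistributed.  Random codons are
drawn under a fixed internal seed and a small set of codons is pinned so
that the locus reproduces the published annotation behaviour exactly —
the residues named by the recurrent ITD annotations, a TGA stop whose
second base coincides with the 96-bp type's proximal breakpoint (turning
TGA into leucine's TTA, the stop-loss mimicry that first flagged the
variant), hybrid junction codons that recreate (or fail to recreate) the
boundary residue for each duplication type, and junction contexts in
which the published intervals are already canonical.  Every sequence-level
test that does not concern those published strings uses freshly generated
random loci, so nothing else depends on the fixture.

## Read simulation

`simulate_reads()` draws `coverage × L / (2 × read_len)` fragments;
lengths are truncated normal (resampled while shorter than the read),
starts uniform; mate 1 is the fragment 5′ end, mate 2 the reverse
complement of the 3′ end; errors are independent per-base substitutions
with constant quality strings.  Indel errors, PCR duplicates and quality
calibration are deliberately out of scope: substitutions are what
exercise the clip-matching robustness without complicating the aligner.

Each fragment's haplotype is an independent Bernoulli draw:
`hemizygous` samples use `mutant_fraction` directly (tumour purity on a
single-copy locus), `heterozygous` samples halve it (two alleles mixed
1:1 within the tumour fraction), `normal` samples never draw the mutant.
The realized mutant read fraction is therefore binomial around the
requested value — the convention the EM quantifier is calibrated against
(see below).  Defaults: 2 × 100 bp pairs, fragment 300 ± 50 (a free
choice; no empirical insert distribution is being matched), error rate
0.005.

## Alignment

The aligner is a Smith–Waterman/Gotoh local aligner (match +1, mismatch
−2, gap open −4 plus −1 per gapped base, soft clipping of read ends
free), implemented in C++ and exposed batch-wise.  Small problems
(≤ 150,000 DP cells) are solved exhaustively; larger references use exact
16-mer seeding with windowed DP around candidate diagonals, and a read
with no seed hit is reported unaligned, as conventional seeded aligners
do.  A read whose best score falls below `0.6 × read length` is an
unmapped record; these thresholds make junction-crossing reads clip
rather than gap, and push deeply-straddling reads (overhang beyond ~40
bases) into the one-mate-unmapped discordant class.  Tie-breaking is
deterministic (first maximal cell in row-major order; forward strand on
orientation ties).  The suite checks score equality against an
independent plain-R dynamic-programming oracle on small problems.

## ITD detection

Detection follows the clip-and-realign logic:

1. **Harvest** terminal soft clips of length ≥ 10 from mapped records,
   keeping the clip side and its anchor (first/last aligned base).
   Unmapped mates of mapped reads are first realigned permissively (no
   reporting threshold) and their clips folded in — the local
   realignment of discordant mates that reveals junctions the mapping
   threshold hides.
2. **Match** each clipped subsequence back to the reference within a
   500 bp window of its anchor (best ungapped placement, ≥ 90% identity,
   allowing up to 12 skipped non-templated bases at the junction side of
   the clip).  A right-clip hit landing at or upstream of its anchor is
   the tandem-duplication signature; the skipped bases are the
   junctional-insertion candidate.  The matched span may be shorter than
   the harvest minimum (floor 6) so that a clip barely above 10 bases can
   still resolve a 3-base insertion.
3. **Reconstruct**: every matched clip proposes `(interval, insertion)`;
   candidates are canonicalized (below) and tallied; the winner needs 3
   supporting reads.  If several candidates reach support — which happens
   at junctions whose flanks carry short repeats, where the aligner's
   clip placement is bistable — the supporting reads are realigned
   against each candidate's reconstructed mutant haplotype and the
   best-fitting candidate kept; only an exact tie is an error.
4. **Allele fraction**: junction-clipped reads divided by reads that span
   the proximal junction collinearly with ≥ 10 aligned bases on each
   side, clamped to [0, 1].  Each allele copy contributes exactly one
   collinear crossing of that site (the wild-type allele its own, the
   mutant its second copy), while only the mutant contributes clipped
   reads, so the ratio estimates the mutant molecule fraction; a
   hemizygous pure-mutant simulation measures ≈ 0.96.
5. **Corroboration**: realigned discordant mates are piled up
   per-position; the peak is every position above `median + 3 × MAD` of
   the profile and an absolute floor of 3 reads (the floor keeps an
   all-zero ITD-free profile from producing spurious peaks).  The peak
   interval overlaps the true duplication and its height grows with the
   mutant fraction.

Defaults (clip length 10, support 3, identity 90%, radius 500) are
choices of this implementation — saturating at 100× coverage while
letting single-error clips still match — not published values.

## Canonical representation and annotation

A duplication-plus-insertion description is not unique: bases can slide
between the insertion and either end of the duplicated interval, and a
pure duplication can slide along a repeat.  `canonical_itd()` first
minimises the insertion (maximal templating), then shifts the junction
transcript-3′-most, matching the HGVS convention of reporting
duplications at their most 3′ equivalent position; the tests verify it
against a brute-force enumeration over every equivalent description.
Published genomic breakpoints are treated as canonical as printed, and
the fixture is constructed so that they are.

Protein annotation translates the mutant CDS through to the first
in-frame stop — running into the modeled 3′-UTR when the duplication
disrupts the stop codon — trims the longest common prefix, then suffix,
against the reference protein, and decomposes the inserted peptide as the
maximal suffix matching the reference segment ending at the trim point
(the duplicated peptide) plus a residual prefix.  The residual is empty
for a clean duplication; with non-templated nucleotides present it is
reported as a peptide insertion (`p.X#_Y#insZ+p.A#_B#dup`); for a pure
duplication whose junction codon is a reference-base hybrid it is a
single junctional missense (`p.X#Y+p.A#_B#dup`).  This decomposition
order — duplication first, then insertion, then missense — is the unique
one reproducing all three published annotation patterns simultaneously.
Frameshift alleles are refused with a `frameshift` status rather than
annotated.

## Somatic filtering

`call_somatic()` retains a merged tumour/normal record iff variant ratio
> 0.05, tumour depth > 50, tumour alt reads > 6 and normal alt reads
< 4 — strict inequalities, so boundary equality rejects; all four
thresholds are configurable.  "Variant coverage in normal" is read as a
read count, matching the units of the other two coverage thresholds.
Records with missing depth fields are rejected individually with a
reason.

## EM quantification of mutant vs wild-type expression

`build_competing_refs()` rebuilds the modified-transcriptome trick: a
wild-type reference holding the last six exons plus the first 304 bases
of 3′-UTR, and a mutant reference with the ITD bases added.  Reads are
scored against both (best ungapped placement, either strand; matches at
`log(1−e)`, mismatches at `log(e/3)`; identity < 90% ⇒ incompatible), so
junction reads are compatible only with the mutant while shared-region
reads split.  The EM is the standard two-component mixture with
effective lengths `L − fragment_mean + 1` (floored at 1): E-step
assignment ∝ fraction × likelihood ÷ effective length, M-step fractions ∝
expected counts, convergence at 10⁻⁶ on fractions within 1,000
iterations, log-likelihood non-decreasing by construction.  `fractions`
is each reference's share of expressed reads; `abundance_fractions`
divides by effective length and renormalizes, undoing the length bias
when comparing molecule abundances of references with different lengths.

Calibration, measured over 10 seeds × 4 fractions per geometry: with
duplications comparable to the read length (the 87–114 bp regime of this
locus, against 100 bp reads) the estimator recovers the simulated mutant
fraction essentially unbiased (mean error ≤ 0.01, SD ≈ 0.01 at 20,000
reads on a 603 nt locus with fragment 200 ± 30 — the geometry the
recovery tests use).  This is a genuine limitation of the desk-scale
model, not an accident: best-placement, single-read scoring cannot be
simultaneously consistent for the pinned-read rate (∝ read length) and
the length correction (∝ duplication length), and for duplications much
longer than a read the estimate is biased low (measured ≈ −0.09 at
dup 120 with mismatched conventions).  A full fragment-level position
marginalization with an insert-size model — what a production quantifier
does — would remove the restriction.  At the mutant-fraction boundary
(fraction 1.0) convergence is geometric with a rate close to 1, so runs
on long references may hit the iteration cap a fraction of a percent
short of 1.0; the cap is configurable.

## Expression recipe

`filter_genes()` keeps genes with mean FPKM strictly above 1.5 and
coefficient of variation strictly above 0.3 (sample standard deviation;
the population/sample choice is undocumented upstream, so the sample form
is used and stated).  An optional identifier-prefix filter drops RPL/RPS
ribosomal genes.  `cluster_samples()` is UPGMA over `1 − Spearman`
distance (average ranks on ties) implemented directly so that the tie
rule is explicit — equal-distance pairs merge by lexicographically
smallest member labels — and cross-checked against `hclust(method =
"average")`; the result is a standard `hclust` object, exportable as
Newick.  `signal_to_noise_rank()` scores `(μ_A − μ_B)/(σ_A + σ_B)` with
each σ floored at `0.2·|μ|` (0.2 when μ = 0), the customary default of
the metric in enrichment software, configurable via `floor_frac`.

## What the simulations do and do not show

The generator emulates the statistical structure the detector relies on —
junction-crossing clips, discordant mates, coverage, allele fraction,
hemizygous vs heterozygous states — under clean assumptions: uniform
fragment sampling, substitution-only errors, a single isolated locus, no
alignment ambiguity beyond the locus itself.  Passing tests therefore
demonstrate the algorithms' correctness under the stated model, not
robustness to mapping artefacts of a full genome, splice isoforms,
GC-coverage bias, indel errors or library chemistry; applying the caller
to real BAMs would additionally need those confounders handled upstream.
Cohort-scale analyses (clustering tens of tumours over ~12,000 genes,
enrichment statistics) are exercised here on planted-structure matrices
at desk scale, with problem sizes chosen to keep the whole suite fast:
50 detector round-trips at 100× on ~1.5 kb loci, 20,000 reads per EM
recovery, 100 seeded clustering runs.

## Worked example

```{r example, eval = FALSE}
model <- synthetic_bcor_locus()
allele <- allele_spec(5138, 5224, "TGT")      # 87-bp dup + TGT insertion
cfg <- sim_config(seed = 42, coverage = 100, mutant_fraction = 1)
sim <- simulate_reads(model, allele, cfg)
aln <- align_pairs(sim, model)
calls <- annotate_calls(detect_itds(aln, model), model)
calls[, c("cdna", "protein", "vaf", "clip_support", "in_frame")]
quantify_itd(model, allele, sim, max_iter = 5000)
```
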