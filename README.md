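# itdseq

Detection, annotation and quantification of internal tandem duplications
(ITDs) from short-read sequencing of a single target locus.

## The problem

ITDs — in-frame duplications of a gene segment inserted in tandem next to
their template copy — are systematically under-called by standard
short-read pipelines: reads crossing the duplication junction are
soft-clipped or discarded as discordant mate pairs, and what survives can
masquerade as a point variant near the breakpoint.  The motivating case
is the X-linked *BCOR* gene in pediatric clear cell sarcoma of the
kidney, where recurrent 87–114 bp in-frame ITDs cluster in the terminal
coding exon (targeting the C-terminal PUFD domain, aa 1,701–1,755),
occasionally interrupted by a short non-templated junctional insertion,
and — the locus being X-linked — can replace essentially all wild-type
expression in hemizygous tumours.

`itdseq` implements that discovery workflow as a tested desk-scale
pipeline:

* **locus model** — minus-strand genomic ⇄ coding-DNA ⇄ protein
  coordinate transforms (per-exon affine map `c = A − (g − g0)`);
* **simulator** — paired-end 2×100 bp reads over wild-type/mutant
  haplotypes with configurable coverage, fragment distribution, error
  rate, mutant fraction and hemizygous/heterozygous states, with ground
  truth;
* **aligner** — Smith–Waterman/Gotoh with free end clipping (match +1,
  mismatch −2, gap open −4, extend −1; reporting threshold 0.6 × read
  length), C++ with exact-seed windowing;
* **detector** — soft-clip harvesting, local clip realignment, tandem
  reconstruction with non-templated-insertion recovery, canonical
  (3′-most, minimal-insertion) representation, allele fraction, and a
  discordant mate-pair coverage-peak corroboration;
* **annotator** — linked `chrX:…–…` / `c.A_Bdup` (+`insNNN`) /
  `p.…dup`-style descriptions, reproducing the clean-dup,
  dup+insertion and dup+junctional-missense patterns;
* **somatic filter** — tumour/normal thresholds (ratio > 0.05, tumour
  depth > 50, tumour alt > 6, normal alt < 4, strict);
* **EM quantifier** — competing wild-type/mutant references (last six
  exons + 304 bp 3′-UTR) with effective-length-corrected
  expectation-maximization of mutant vs wild-type expression;
* **expression recipe** — FPKM mean/CV filtering, UPGMA clustering on
  `1 − Spearman` distance, and signal-to-noise gene ranking.

## Worked example

Simulate a hemizygous tumour carrying the 87-bp duplication with a TGT
junctional insertion on the bundled synthetic BCOR-like locus, align,
detect and annotate:

```r
library(itdseq)
model  <- synthetic_bcor_locus()
allele <- allele_spec(5138, 5224, "TGT")   # 87-bp dup + 3-bp insertion
cfg    <- sim_config(seed = 42, coverage = 100, mutant_fraction = 1)
sim    <- simulate_reads(model, allele, cfg)
aln    <- align_pairs(sim, model)
calls  <- annotate_calls(detect_itds(aln, model), model)
calls[, c("cdna", "protein", "vaf", "clip_support", "in_frame")]
#>                               cdna                            protein       vaf
#> 1 c.5138_5224dup+c.5224_5225insTGT p.V1741_E1742insV+p.L1713_V1741dup 0.9589041
#>   clip_support in_frame
#> 1           70     TRUE
calls$gdna
#> [1] "chrX:39,911,406–39,911,492"
```

The detector reconstructed the duplicated interval, recovered the
non-templated `TGT` between the copies, annotated the allele as an
in-frame duplication with a one-valine junctional insertion, and measured
an allele fraction near 1 — the wild-type allele is virtually
undetectable in a hemizygous pure-mutant sample.  Quantifying mutant vs
wild-type expression with the two-reference EM:

```r
quantify_itd(model, allele, sim, max_iter = 5000)
#> EM quantification: mutant 0.9830 / wild-type 0.0170 (4464 reads, 5000 iterations, not converged)
```

i.e. ≈ 98% of locus expression is contributed by mutant transcripts
(convergence at the simplex boundary is geometric and slow; the estimate
moves only in the fourth decimal).

A thin command-line front end over the same functions ships in
`inst/scripts/itd-tools.R` (`simulate`, `detect`, `filter-somatic`,
`quantify`, `profile` subcommands).

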