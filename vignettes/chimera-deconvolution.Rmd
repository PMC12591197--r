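---
title: "Methods: cell-layer deconvolution of periclinal chimeras"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-layer deconvolution of periclinal chimeras}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chimerase)
```

## The inference problem

A periclinal chimera's organs are genotype mosaics: the L1 meristem
layer comes from one donor genotype ("donor O" throughout this package)
and the L2/L3 layers from the other ("donor C"). Bulk RNA-seq of a
chimera tissue therefore samples a *mixture* of two transcript pools.
chimerase estimates the mixing fraction and assigns genes to layers
using only the allele identity of reads at donor-diagnostic SNPs.

The analysis rests on three assumptions worth stating explicitly:

1. **Diagnostic sites are truly diagnostic.** Both donors must be
   homozygous, for different alleles, at every site used. Only then does
   a read's allele identify its donor. This is why
   `find_diagnostic_sites()` requires homozygosity in *both* donors
   rather than merely different genotypes: a heterozygous donor site
   makes chimera allele counts uninterpretable as layer evidence, so the
   stricter rule is the only one that supports the downstream
   arithmetic.
2. **Reads are exchangeable within a site.** Each read at a diagnostic
   site carries the donor-O allele with a probability determined by the
   gene's layer usage and the miscall rate, independently of other
   reads. Mapping bias toward the reference allele, which violates this,
   is not modelled (see Limitations).
3. **Shared genes express proportionally to layer amounts.** The
   tissue-level mixture fraction is identified from genes expressed by
   all layers; layer-specific genes carry `f = 1` or `f = 0` instead of
   the tissue fraction and are handled at gene level, not pooled into
   the tissue estimate.

## Diagnostic-site discovery

`find_diagnostic_sites()` intersects the two donors' call sets and keeps
sites where both donors are homozygous (by the genotype field, never
re-derived from allele depths — the caller's genotype is the published
unit of evidence), the alleles differ, and both records pass quality
filters. The defaults in `diagnostic_filters()` are conventional hard
thresholds, not estimates: minimum depth 10 reads and minimum site
quality 30 (Phred scale) per donor, biallelic records only, SNPs only
(substitution alleles of length 1; chimera allele counting is only
well-defined for base-identity evidence).

Sites present in only one donor's call set are excluded by default:
per-donor call sets of unknown completeness do not license reading
absence as homozygous-reference. For callers that emit all-sites VCFs,
`absent_means_homref = TRUE` enables the alternative convention, taking
the other donor's REF as the missing donor's allele.

Coordinate conventions are kept native to each format and converted in
exactly one place: VCF positions are 1-based, BED intervals 0-based
half-open, and a site at VCF position `P` overlaps an interval iff
`start <= P − 1 < end`.

## Origin classification

`classify_sites()` labels each counted site `O_ONLY`, `C_ONLY`, `BOTH`
or `UNINFORMATIVE`. An allele counts as *present* only if it passes both
an absolute floor (`min_allele_reads = 3`) and a relative floor
(`min_allele_frac = 0.05` of informative reads). Two floors are used
because either alone misbehaves across the depth range real tissues
produce: a pure read-count rule over-calls presence at high depth
(3 stray reads out of 2,000), while a pure fraction rule over-calls at
low depth (1 read out of 12 is 8%). Sites below `min_total = 10`
informative reads, or with more than `max_other_frac = 20%` third-allele
reads (a mismapping signature), are voided. Zero-coverage diagnostic
sites are *retained* as `UNINFORMATIVE` rather than dropped, so category
counts always sum to the number of diagnostic sites and the expressed
fraction of sites remains reportable.

## Composition estimators

Published chimera proportions do not always state whether they are
SNP-count shares or read-weighted fractions, so `estimate_composition()`
reports three estimators side by side and makes the choice auditable:

* **`site_share`** (the pipeline default, matching the convention of
  counting SNPs per donor): the fraction of informative sites resolving
  to donor C. Sites called `BOTH` contribute their donor-C read fraction
  `1 − f_O` rather than a flat ½, so deeply covered shared sites carry
  their actual evidence.
* **`read_fraction`**: pooled `Σ n_C / Σ (n_O + n_C)`. Depth-weighted,
  zero-parameter, but biased by `ε(1 − 2p)` when miscalls exist.
* **`binomial_mle`**: maximises `Σ_i log Binomial(n_{C,i} | n_i, q(p))`
  with `q(p) = p(1 − ε) + (1 − p)ε`. This corrects the read fraction for
  the miscall rate and supplies a log-likelihood. The default
  `ε = 0.005` is a typical short-read substitution error rate; it is a
  configuration value, not a fit.

### Numerical notes

Because every site shares the same success probability `q(p)`, the
log-likelihood factorises through the pooled sufficient statistics
`S_C = Σ n_C` and `S = Σ n`; the binomial-coefficient term is constant
in `p` and computed once. The maximiser is located by a 1,001-point
coarse grid over `[0, 1]` followed by bracketed one-dimensional
refinement (`stats::optimize`, tolerance `1e-9`) on the interval framing
the best grid point — deterministic and derivative-free, which is all a
smooth unimodal 1-D likelihood needs. If refinement cannot improve on a
boundary grid point the grid point is kept. At `ε = 0` the closed form
`p̂ = S_C / S` is returned exactly, and the test suite pins the
optimizer to an independent per-site `10^6`-point grid search elsewhere.
`ε ≥ 0.5` is rejected: beyond that the allele labels are no longer
identifiable.

Degenerate inputs raise typed estimation errors rather than `NaN`: no
informative sites (site share), no informative reads (read fraction,
MLE), or a zero tissue-L1 fraction (L1 normalisation).

### Bootstrap intervals

`bootstrap_ci()` resamples *sites* with replacement — the site, not the
read, is the exchangeable unit, since reads within a site share its
depth draw — and takes percentile quantiles of the re-estimated `p_C`
over `B` replicates (default 1,000; level 0.95). Resamples with zero
informative reads are redrawn and the redraw count is reported, so
degenerate resamples can never silently collapse an interval. All
resampling is driven by an explicit seed and reproducible.

## Gene-level layer analysis

`pool_gene_counts()` sums allele counts over each gene's diagnostic
sites; sites overlapping more than one annotated gene are excluded from
pooling (their attribution is ambiguous) but retained for tissue-level
composition, where gene identity is irrelevant. The L1-normalised
expression percentage is reconstructed as

```
pct_L1 = min(f_O / p_O, 1) × 100
```

with `p_O` the tissue-level L1 fraction from the composition stage — a
gene's donor-O allele frequency measured against the amount of L1 tissue
present, capped at 100%. This normalisation is deliberately isolated in
one small function (`pct_expression_l1()`) because it is a
reconstruction of a verbal description rather than a published formula;
anyone preferring a different normalisation can substitute one line.

`classify_gene_layer()` mirrors the origin module's presence logic at
gene scale: `f_O ≥ 0.95` → L1-specific, `f_O ≤ 0.05` → L2/L3-specific,
in between → shared, and genes with fewer than 20 pooled informative
reads → unclassified. At the simulator's default depth (50× per site,
several sites per gene) a truly layer-specific gene sits at
`f_O ≈ 1 − ε ≈ 0.995`, comfortably inside the 0.95 band, while a shared
gene at any plausible mixture fraction sits far from both bands; the
thresholds are symmetric so donor relabelling exactly swaps the two
specific classes.

Marker genes with *declared* layer specificity (PDF1 for L1, SYS for
L2/L3 — declarations are knowledge brought to the analysis, never
inferred from the data being tested) drive `infer_structure()`: if all
L1 markers resolve to one donor and all L2/L3 markers to the other, the
chimera is called `PERICLINAL` with that donor-to-layer mapping. Any
uninformative marker yields `UNDETERMINED`; conflicting markers —
including a supposedly layer-specific marker expressing both alleles —
yield `INCONSISTENT`.

## What the simulator emulates

`simulate_chimera()` generates the full data-generating situation the
pipeline assumes: two donors homozygous for different alleles at every
diagnostic site, a chimera tissue whose reads at a site of gene *g* are
donor-O with probability `f_g(1 − ε) + (1 − f_g)ε` (with `f_g = 1`,
`0`, or `p_L1` for L1-specific, L2/L3-specific and shared genes), site
depths drawn Poisson (default, mean 50) or negative-binomial for
overdispersion, and the two marker genes always planted. The miscall
draw is two-stage — first the read's layer of origin, then a possible
miscall — so the truth records both pre-error and observed counts, and
the observed count is still exactly binomial marginally. Decoy sites at
which the donors share a genotype are planted outside gene bodies so the
diagnostic-site filter is exercised rather than assumed. Everything is
reproducible byte-for-byte from the seed, and `write_simulation()`
serialises to standard VCF/BED/TSV that round-trip through the package
readers identically — the simulator doubles as the fixture generator
for the whole test suite, with `truth_check()` asserting
self-consistency of any run.

Real data differ from this generative model in ways the simulator
deliberately does not imitate: no mapping bias toward the reference
allele, no isoform structure or intra-gene expression variation beyond
depth, no linkage between neighbouring sites, no genotyping error in the
donor call sets, and no third-allele noise at diagnostic sites (decoys
and hand-built fixtures cover the `n_other` paths instead). Passing the
simulation-based suite therefore demonstrates correctness of the
inference given the model — not robustness to alignment artifacts,
which upstream QC must handle.

## Validation design and problem sizes

The acceptance suite validates the pipeline at a standard study scale
chosen once: mixtures at donor-C fractions 0.7981, 0.5231 and 0.7342
(the three fruit-tissue proportions used as planted truth) over 1,000
shared-gene diagnostic sites (250 genes × 4 sites) at mean depth 50 and
`ε = 0.005`, 100 replicates per fraction for parameter recovery
(±0.02 band), 200 replicates at `B = 500` for bootstrap calibration
(90–99% observed coverage band), 10 replicates for gene-classification
precision/recall (≥0.9 with 10% planted specifics of each kind), and 50
random count sets for optimizer-vs-oracle agreement (≤ `1e-5`). Because
the tissue-level estimators assume the shared-gene mixture model, these
checks restrict the pooled counts to sites of genes planted as shared;
the always-present marker genes are layer-specific by construction and
would otherwise shift the pooled allele fraction by their site share
(about 0.002 here — small, but systematic).

One caveat surfaced by this design: at 1,000 sites the MLE's sampling
standard deviation is ≈0.002, so the ±0.02 recovery band is loose, while
the bootstrap calibration band is the genuinely informative check.

## Limitations

* Two donors only; the L2 vs L3 distinction is unidentifiable when both
  derive from the same donor, as in the motivating chimera.
* No correction for reference-mapping bias; if donor O is the reference
  genotype, `f_O` can be inflated at poorly mappable sites. Competitive
  or variant-aware alignment upstream mitigates this.
* `site_share` treats sites as exchangeable units, which down-weights
  deeply covered genes relative to `read_fraction`; the package reports
  all three estimators precisely because the right weighting is a
  judgement call.
* The L1-normalisation formula is a documented reconstruction (see
  above), and marker-gene percentages computed with it are demonstration
  outputs, not calibrated quantities.
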