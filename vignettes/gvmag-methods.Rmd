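---
title: "Models and conventions of the gvmag toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions of the gvmag toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvmag)
```

`gvmag` recovers giant-virus (*Nucleocytoviricota*) genomes from binned
metagenomic assemblies and quantifies their population ecology and
microdiversity. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic-data generators emulate, and
the numerical choices that make runs reproducible.

## Screening: the core-gene density index

Giant-virus genomes carry a compact set of conserved marker genes
(NCVOGs), and the number of core genes scales with genome size. The
density index relates the summed conservation weights of the markers
detected in a bin to its size:

$$\mathrm{index} = \frac{\sum_{k \in \mathrm{detected}} w_k}
  {\log_{10}(\text{genome size in bp}) - 4}$$

A bin is a giant-virus candidate when the index strictly exceeds the
threshold (default **5.75**), a value sitting in the empirical gap that
separates reference viral from cellular genomes. Because the gap is wide,
the strict/non-strict reading of the boundary is immaterial in practice;
we use strict `>` as the conservative choice. Marker presence is binary
per bin: the numerator sums weights over distinct markers, not copies.
The denominator is positive only above 10 kb; smaller bins are reported
as *not evaluable* rather than silently dropped. The 20-marker weight
table is dataset-specific (conservation per viral family, weights in
[0, 1]); the shipped default is a placeholder of 20 unit-weight markers
(the five hallmark genes — MCP, PolB, TFIIB, TopoII, A32 — plus generic
slots) that users should replace with their own profile.

## Refinement: a four-rule quality-control cascade

Each contig receives a **characteristic score** in [0, 4]: one point per
taxonomic classifier (up to three) assigning it to the target lineage,
plus one point for any hit against the marker HMM collection. The cascade
then applies:

1. **Bin removal** — a bin is discarded only when it lacks *all five*
   hallmark genes *and* strictly more than 90% of its contigs score 0.
   The conjunction matters: one hallmark rescues a bin regardless of its
   score profile.
2. **Score-0 stripping** — remaining score-0 contigs are treated as
   misbinned cellular sequence and removed.
3. **Outlier decontamination** — a contig is a coverage outlier outside
   [Q1 − 1.5·IQR, Q3 + 1.5·IQR] (quartiles by linear interpolation,
   `quantile(type = 7)`; Tukey hinges differ negligibly, but the method
   is fixed for reproducibility) or a composition outlier when its score
   on PC1 of the bin's column-standardised tetranucleotide matrix exceeds
   ±2.5 SD. Outliers are removed only at characteristic score exactly 1;
   scores ≥ 2 are treated as positive evidence of viral origin. Bins with
   fewer than four contigs skip this step (quartiles are meaningless) and
   are flagged.
4. **Chimera resolution** — a bin whose coverage coefficient of variation
   (sd/mean across member contigs) exceeds 1 *and* that carries a
   designated single-copy marker in ≥ 2 copies is a chimera suspect. Its
   contigs are clustered on standardised coverage ⊕ tetranucleotide
   features (Ward linkage, Euclidean distance, cut at k = 2). The split
   is accepted only if **both** clusters pass all four criteria: total
   length > 40 kb, ≥ 1 single-copy marker, strictly > 50% of contigs
   scoring 4, and ≥ 80% of classified contigs sharing one species label.
   Otherwise the bin is emitted unsplit with the failed criteria as
   reason codes — refusing a split is the safe default.

Composition space is the 136 canonical (reverse-complement-collapsed)
4-mer frequencies on the forward strand, the standard binning convention.
The coverage CV is computed across contigs within the bin's source
sample; the alternative across-samples reading does not detect
mixed-genome bins, which is the purpose of the rule. The 80%
species-label consistency value is our operationalisation of "consistent
species-level taxonomy" and is configurable. Every removal emits a
machine-readable audit row — in an automated pipeline, auditability
substitutes for manual curation.

## Dereplication at the 95% ANI species boundary

Pairwise ANI among refined giant-virus MAGs is bimodal, supporting 95%
ANI as an operational species boundary. Clustering is two-stage: a
MinHash sketch estimator (canonical 21-mers, bottom-1000 sketch, Mash
transform $\mathrm{ANI} = 1 + \ln(2j/(1+j))/k$) forms coarse components
by single linkage at ≥ 90%, then a k-mer containment estimator
($\mathrm{ANI} = C^{1/k}$ with $C = |A \cap B| / \min(|A|,|B|)$, robust
to incomplete genomes) drives average-linkage clustering cut at ≥ 95%.
The precise backend is pluggable so an external aligner can be hooked in.
The rolling hash is a fixed polynomial hash modulo a prime below $2^{26}$
(keeping every intermediate exactly representable in doubles), so ANI
estimates are bit-reproducible across platforms with no RNG involved.
Representatives maximise $\log_{10} N50 + 0.5\,\log_{10}(\text{size}) +
\text{centrality}$ (centrality = mean precise ANI to the other cluster
members); the weights are this package's convention, configurable, with
exact ties broken to the lexicographically smaller id.

## Phylogeny-informed quality assessment

Relative evolutionary divergence (RED) normalises node depth on a rooted
guide tree: the root is 0, every leaf is 1, and a child at branch length
$d$ from its parent with mean node-to-tip distance $u$ has
$\mathrm{red} = \mathrm{red}_p + \frac{d}{d+u}(1 - \mathrm{red}_p)$.
Clades are maximal subtrees whose root is an internal node with RED at or
above the threshold (default **0.65**, roughly genus/family rank) while
its parent is below; the threshold applies to the clade root, not mean
member RED, matching how rank thresholds are used in RED-based
taxonomies. Leaves with no qualifying internal ancestor are long branches
and stay unassessed.

Within a clade, core genes are orthologous groups present in strictly
more than half of the members. Two per-genome scores follow:

- **consistency** = core OGs present in the genome / clade core OGs
  (a completeness proxy);
- **redundancy** = excess copies over the clade modal copy number, summed
  over core OGs, divided by the core OGs the genome possesses (a
  duplication/contamination proxy).

"Redundant genes" is read as excess gene *copies*
($\sum \max(0, c - \mathrm{mode})$) rather than the count of offending
families; the modal copy number breaks ties toward the smaller value, and
both numerator and denominator live on the core-gene universe so the two
scores share one frame of reference. A genome holding no core OG gets
consistency 0 and an undefined redundancy, flagged rather than forced to
a number.

## Population dynamics

Abundance is RPKM (reads per kb of genome per million sequenced reads).
Presence requires coverage breadth strictly above 50%. The *abundant*
subset of a sample cumulates MAGs in decreasing relative abundance until
their summed squared relative abundances reach 80% of the sample's
Simpson concentration $\sum p_i^2$; the alternative reading (cumulating
relative abundance itself) is available behind a configuration flag.
Community recurrence uses Sørensen–Dice similarity on presence sets over
all sample pairs, with no smoothing; samples are averaged into calendar
months before time-course analyses because sampling frequency is uneven.

Niche classification works on the fixed January 2017 – September 2018
month axis with 8-month windows sliding by one month. *Persistent* means
a run of strictly more than four (≥ 5) consecutive present months inside
one window — any such run fits some window on this axis, so the rule
reduces to the run length. *Seasonal* requires all 2017 occurrences
inside one 8-month calendar window of 2017, a reappearance in the same
calendar window of 2018, and absence in every observed 2018 month outside
it (windows are calendar-aligned across years, not day-offset-aligned).
MAGs present in January and September 2017 fit no window and can never be
seasonal. Remaining MAGs are *sporadic* (2017 only) or *other* (both
years); MAGs absent throughout 2017 are excluded. Niche breadth is
Levins' index $B = 1/\sum_i p_i^2$ over monthly relative abundances,
ranging from 1 (single-month specialist) to the number of occupied months
(uniform generalist). Environmental associations use Spearman rank
correlation with Benjamini–Hochberg correction across variables.

## Microdiversity

Per-site allele frequencies come from A/C/G/T read counts (0-based
positions). Nucleotide diversity per site is $1 - \sum_X f_X^2$
(range 0 – 0.75); the genome-wide value averages over SNV sites. SNV
calling requires depth ≥ 5× plus minor-allele support of ≥ 2 reads and
≥ 5% frequency — the depth rule is the method's core constraint, the
allele thresholds are the common strain-profiling defaults and are
configurable. SNV density is sites per Mb.

Between samples, the per-site distance is
$\pi(a,b) = \sum_X a_X (1 - b_X)$ — the probability that two reads drawn
from the two samples differ — and satisfies $\pi(a,a) = \mathrm{ND}(a)$
algebraically (enforced as a test at $10^{-12}$). The fixation index
averages $\pi$ over the shared-site universe:

$$f_{st}(a,b) = 1 - \frac{(\bar\pi(a,a) + \bar\pi(b,b))/2}{\bar\pi(a,b)},$$

with microdiversity similarity $1 - f_{st}$. The ratio-of-averages form
(not the average of per-site ratios) is deliberate: it weights sites by
their diversity rather than letting near-monomorphic sites dominate. The
default shared-site universe is positions called SNV in *at least one* of
the two samples and covered at depth in both: requiring the SNV in both
samples would hide sweeps (a site fixed differently in the two samples is
exactly the signal $f_{st}$ should see), while the broadest co-covered
universe is available for fixed-difference analyses. When the
between-sample distance is 0 the pair is monomorphic and identical;
$f_{st}$ is defined as 0 with a flag rather than propagating NaN.
Microdiversity time courses are restricted to samples where the MAG
passes the abundance rule, because allele frequencies from a handful of
reads are noise.

## What the generators simulate — and what they do not

All fixtures flow from one integer seed with per-entity substreams keyed
by stable ids, so adding a bin never shifts another bin's draws and
identical specifications are byte-identical.

- `sim_community()` plants viral bins (100 kb – 1 Mb, all 20 markers,
  high classifier agreement), cellular bins (2 – 6 Mb, ≤ 2 non-hallmark
  markers, score 0), optional contaminant contigs (deviant coverage and
  composition, scores ≤ 1) and chimera bins (two genomes at ~10× vs
  ~200× coverage with duplicated single-copy markers). Composition is
  modelled directly in canonical tetranucleotide space: each genome draws
  an iid base model whose expected 4-mer profile anchors tight
  per-contig Dirichlet draws; contig sequences, when requested, are
  drawn from the same base model. Real genomes have autocorrelated,
  repeat-laden composition and assembly artefacts that this model does
  not reproduce — passing tests demonstrate that the rules fire as
  specified on coherent signal, not that the thresholds are optimal for
  any particular environment.
- `sim_snv_profiles()` is a two-haplotype mixture: at each divergent site
  reads derive from haplotype 1 with probability $\theta$, depth is
  Poisson, and error $\epsilon$ redistributes reads uniformly. At error 0
  and depth $d$ the expected site ND is exactly
  $2\theta(1-\theta)(1 - \mathrm{E}[1/d])$ — the $(1 - \mathrm{E}[1/d])$
  factor is the finite-depth sampling effect of the plug-in ND
  estimator, and parameter-recovery tests compare against this exact
  expectation (about 2% below the infinite-depth value at 50×). For the
  same reason the fixation index between samples with equal $\theta$ has
  expectation $\mathrm{E}[1/d]$ rather than 0. Real populations have more
  than two haplotypes, linkage, and non-uniform error; the fixture
  isolates the estimator arithmetic.
- `sim_occurrence()` builds one noise-free profile per niche archetype
  (the *other* archetype uses the January + September pattern that no
  8-month window covers); `sim_clade_fixture()` drops exactly
  `round(d · n_core)` core OGs per genome so the realised dropout rate
  equals the nominal one (a variance-control choice; Bernoulli dropout
  would add binomial noise to the recovered mean consistency), and hangs
  the clade beside a long-branch outgroup to exercise the unassessed
  path; `sim_seasonal_community()` and `sim_allele_cycling()` plant exact
  12-month periodicity to probe the 365- vs 182-day lag contrast.

## Problem sizes and runtime

The shipped tests and the acceptance script use deliberately small
problems — communities of ~10 bins, 80 – 100 kb dereplication genomes,
1000-site SNV tables, 24-month time courses — chosen so the full suite
runs in well under a minute per module while still leaving every decision
rule and estimator statistically identifiable (e.g. 3 Monte-Carlo
standard errors resolve the finite-depth ND correction at 1000 sites).

## Known limitations

- The weight table and marker lists are placeholders; results on real
  data depend on supplying the curated 20-NCVOG weights and the full HMM
  collection.
- The containment/sketch ANI estimators assume moderately complete,
  low-repeat genomes; highly repetitive or very fragmented genomes
  deserve an alignment backend via the pluggable hook.
- Niche classification is tied to the two-year January 2017 – September
  2018 axis by design; other campaigns need the axis generalised.
- BAM pileups, read mapping, orthology inference and tree building are
  out of scope: the package consumes their tabular outputs.
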