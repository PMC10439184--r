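---
title: "Methods: rhodopsin identification, spectral tuning and size-fraction expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhodopsin identification, spectral tuning and size-fraction expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pprscope` analyses proton-pump rhodopsin (PPR) diversity and expression in
metatranscriptomes of mixed prokaryote/eukaryote plankton communities that
were sequenced as two size fractions (0.22–3 µm and 3–200 µm) per water
sample. This vignette documents the models and procedures, the parameters
that matter and why their defaults are what they are, what the synthetic
generator does and does not emulate, and the numerical conventions.

## Identification model

Unigene proteins are searched against a curated reference panel by local
pairwise alignment (Smith–Waterman, BLOSUM62, gap open 11 / extend 1 — the
conventional protein-search defaults). Because no external search engine is
invoked, E-values are computed from the raw alignment score with fixed
Karlin–Altschul constants for gapped BLOSUM62 statistics (λ = 0.267,
K = 0.041) over an effective search space of query length × total panel
length. These constants are deliberately frozen: identical inputs give
identical E-values on any machine. A hit is accepted when E < 10⁻⁵ **and**
percent identity > 40, identity being counted over all aligned columns
including gaps (PID1). The best hit per query is the maximal bitscore, with
ties broken by smaller E-value and then lexicographically smaller reference
id, so assignment is fully deterministic. The query inherits the winning
reference's family, domain and taxon.

Two filters gate the catalog:

* **Helix C–F completeness.** A rhodopsin call is only trusted when the
  alignment covers the reference's four central transmembrane helices
  (C–F), stored per panel entry as a 1-based inclusive span. Coverage is
  containment of that span in the reference side of the alignment,
  inclusive at both ends. Since an alignment to a truncated query cannot
  span reference positions the query does not have (gaps cost more than
  they gain), any fixture truncated inside the span fails the check.
* **Low expression.** A unigene is removed only when its TPM is *below*
  0.1 in **every** sample; a single sample at exactly 0.1 keeps it. The
  boundary follows the strict reading of "less than". The filter is applied
  *after* annotation (it governs the subsequent analysis, not the search).

The panel ships with the package. Its entry ids keep the GenBank accessions
conventionally used to anchor the PR, XR and GR clades, but the sequences
are synthetic surrogates (files named `*_synthetic.*`) generated from a
single ancestor with family bases at ~45% divergence and within-family
members at 8–12%, eukaryote PRs forming a subclade at ~20% from the PR
base. This preserves everything the pipeline needs — clade structure,
tuning residues, helix spans, domain labels — without redistributing
database sequences, and it makes the panel a *known* quantity for testing.

## Spectral-tuning classification

The blue/green dichotomy of proteorhodopsins is controlled by one residue
in the retinal pocket: position 105 in conventional PR numbering.
Glutamine there gives a blue absorber (BPR, λmax = 490 nm); methionine or
leucine a green absorber (GPR, λmax = 525 nm). The package maps a query
onto that coordinate system by **global** (Needleman–Wunsch) alignment to
the canonical PR (BLOSUM62, gap open 10 / extend 1): a local alignment
could legitimately stop before the site, silently mis-mapping it. The
query symbol in the alignment column holding canonical residue 105 is the
tuning residue; a gap symbol (`-`) means the query has no residue there.
Classification is a pure function of (residue, family, pump status):
Q → BPR, M/L → GPR, anything else (including `X`, `-`, or a missing
mapping) → unclassified; non-proton-pump families are never classified.
Comparison is case-insensitive.

Which sequence "position 105" refers to is a convention, so the canonical
entry is an explicit, overridable field of the panel (`canonical_pr_id`,
default the green-absorbing eBAC31A08-type entry with leucine at 105). The
residue rule is restricted to the PR family by default: the dichotomy is
defined for proteorhodopsins, and extending it to XR/GR is possible
(`include_xr = TRUE`) but off by default. A secondary tuning site reported
for particular PRs (Cys189) is deliberately not modelled.

Homology-based spectral annotation can be spectroscopically wrong for
specific taxa. The override table (default rows: *Karlodinium micrum* and
*Ceratium fusus* forced to BPR) corrects such calls after classification;
patterns are case-insensitive regular expressions matched against source
taxon and unigene id, overriding is idempotent, and an unmatched pattern
warns rather than errors (a panel without those taxa is not a bug).

## Size-fraction merging and lineage contributions

TPMs from different libraries are internally normalized quantities, so the
small- and large-fraction libraries of one water sample cannot be summed
directly. The merge weights each fraction's TPM by the RNA mass extracted
per liter of seawater from that fraction:

$$\mathrm{merged} = \frac{T_s\,R_s + T_l\,R_l}{R_s + R_l}$$

with $T$ the group TPM sums and $R$ the RNA yields per liter. Only the
yield *ratio* matters, so the mass unit is free (the package documents
µg/L). The formula is a weighted mean — bounded by the two TPMs — and
linear in each TPM argument, so merging commutes with summing unigenes
into groups; the package exploits this by merging at whatever grouping the
user asks for (domain, family, spectral class, taxon) and reports absolute
merged contributions plus percentage shares, which sum to 100 over any
exhaustive disjoint grouping. Replicates are never pooled before merging.
A water sample missing one fraction is computed from the present fraction
alone and flagged, rather than dropped.

## Distance statistics

Community distances default to Bray–Curtis (via `vegan`), environmental
distances to Euclidean on per-variable z-scores, both overridable — the
choice of metric is a convention of community ecology, not part of the
formula being tested. Conventions for degenerate input are explicit: an
all-zero abundance row is at distance 1 from any row with signal and 0
from another all-zero row; zero-variance environmental variables are
dropped with a warning.

The Mantel statistic is the Pearson correlation of the strictly-lower-
triangle vectors; its permutation p-value is one-tailed for positive
association, permutes the row/column order of the second matrix jointly,
and uses the add-one correction $(1 + \#\{r_\pi \ge r_{obs}\})/(1 + N)$ so
p is never zero. An exhaustive mode enumerates all $n!$ relabelings
(guarded at $n \le 8$) and returns the exact fraction. The partial Mantel
statistic correlates the residuals of the two triangle vectors after
simple linear regression on the third matrix's triangle vector, permuting
the second matrix and recomputing the statistic each time. Permutation
comparisons use an absolute tolerance of 10⁻¹² so that the identity
permutation always counts. The implementation is the package's own;
`vegan::mantel` / `mantel.partial` are used in the test suite as an
independent cross-check of the statistic (they agree exactly) — never as
the implementation.

Expression-vs-abundance panels use ordinary least squares with Pearson r
and R² = r², on untransformed values, matching how such panels are
conventionally reported.

## The synthetic generator

`simulate_community()` produces fixtures with *planted* structure so that
every stage of the pipeline can be verified against ground truth:

* **Design.** 2 stations (continental shelf, continental slope) × 3 photic
  depths (SUR, DCM, BOT) × 2 replicates = 12 water samples, each sequenced
  as 2 size-fraction libraries (24 libraries). RNA yields per liter are
  uniform on 0.5–5 µg/L per library.
* **Sequences.** Each rhodopsin unigene is a point-mutated copy of a panel
  entry (default 10% per-site substitution, tuning site protected and then
  set to the planted residue; no indels). 10% of unigenes are random
  decoys. Family composition among prokaryotes (55% PR, 15% XR, 5% GR,
  10% BR, 8% SRI, 7% other) loosely mirrors the observation that PR
  dominates, XR-like pumps follow, and sensory/other rhodopsins are rare;
  eukaryote unigenes are all PR, as dinoflagellate PPRs dominate protist
  rhodopsin expression.
* **Expression.** Each library's TPM vector sums to 10⁶ (decoys absorb the
  remainder). The merged rhodopsin pool per water sample is log-normal
  (median 5000 TPM, sdlog 0.3); the domain split of that pool is planted
  *exactly* (default 70:30 prokaryote:eukaryote, on the merged scale) by
  choosing per-fraction group sums whose yield-weighted mean hits the
  target, with prokaryotes biased toward the small fraction (70–90% of
  their merged contribution) and eukaryotes toward the large (10–30%).
  The alternative `share_stage = "pre_merge"` plants shares per library
  with 3% multiplicative noise, so merged shares recover the target only
  statistically. Within-pool unigene weights are log-normal, redrawn per
  library.
* **Depth trend.** The BPR share of each domain's PR pool is 0.25 / 0.50 /
  0.75 at SUR / DCM / BOT (reversed if configured), so the blue fraction
  of blue+green expression is monotone by construction in every library.
* **Environment.** Phosphate, nitrate+nitrite and silicate are coupled to
  eukaryotic PPR merged abundance through a Gaussian copula at correlation
  `env_effect_r` (default 0.6) with independent residuals per nutrient;
  the log-normal pool makes log-abundance exactly Gaussian, so the copula
  is exact. Depth, temperature and salinity are generated from the depth
  layer and are *not* coupled to the pool. Taxon relative abundances are
  coupled to the corresponding PPR expression (Pelagibacterales ↔
  prokaryote BPR, Flavobacteriaceae ↔ prokaryote GPR, Dinophyceae ↔
  eukaryote PPR) at `abund_effect_r` (default 0.9) on the copula scale and
  then normalized to relative abundances — the observed linear-scale R²
  is therefore attenuated below 0.81, which is the realistic situation.

What the generator does **not** emulate: assembly chimeras and
fragmentation (truncation fixtures are built explicitly in tests), indels,
codon-level evolution (nucleotide fixtures are deterministic
back-translations used only for ORF-translation tests), rRNA depletion
artifacts, compositional coupling between samples, or per-cell rhodopsin
copy number. Passing tests therefore demonstrate correctness of the
*computations* under the stated statistical structure, not robustness to
every artifact of real sequencing data.

## Numerical and testing notes

* Alignment-based operations are deterministic: fixed substitution matrix,
  fixed gap penalties, deterministic tie-breaks in best-hit selection.
* All randomness flows from explicit integer seeds; `simulate_community`
  restores the caller's RNG state.
* Test problem sizes: the identification recovery check runs 500 unigenes
  at 20% divergence; spectral recovery 200 protected-site mutants; Mantel
  calibration 1000 null replicates (199 permutations each, n = 8);
  planted-association detection 100 communities of 60 unigenes with 999
  permutations. The tested eukaryotic pool and nutrients are planted at
  the domain level and are independent of the unigene count, so the
  smaller community size in replicate loops changes runtime, not the
  quantity under test.
* Measured behaviour of the planted-association design: with 12 water
  samples and three nutrients each coupled at r = 0.6, the one-tailed
  Mantel test at α = 0.05 detects the association in roughly 80% of
  seeded replicates (the test suite computes this rate; the null variant
  rejects at ≈ 5%, confirming calibration). Detection rates above 90% at
  this effect size would require more water samples than the 2 × 3 × 2
  design provides — a power limit of the sampling design itself, which
  the package reports rather than masks.

## Known limitations

* Nearest-reference classification replaces phylogenetic placement; a
  query equidistant from two families is assigned by score, not by tree
  topology, and novel families absent from the panel are invisible.
* E-values are calibrated by fixed constants, not by empirical fitting to
  the panel's score distribution; they are internally consistent but not
  comparable to BLAST E-values against NR/NT.
* The blue/green rule is a two-state approximation of a continuous
  spectral-tuning landscape and ignores secondary tuning sites.
* Merged "TPM contributions" are comparable across groups within a water
  sample but are not TPMs of any single library and should be labelled as
  such in downstream reporting.
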