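---
title: "Methods: dosage signal classes, ploidy inference and redundancy analysis for clonal SNP panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage signal classes, ploidy inference and redundancy analysis for clonal SNP panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonepanel)
```

clonepanel analyses clonal, mixed-ploidy germplasm collections genotyped
with a small biallelic fluorescence (KASP-style) SNP array. This vignette
is the package's account of the science: the models, the tunable
parameters, the synthetic-data generator the tests rely on, and the
numerical choices made where the design was genuinely open.

## The dosage signal-class model

A competitive allele-specific PCR assay reports, per accession and
biallelic locus, a two-channel fluorescence signal whose position depends
only on the *fraction* of the alternate allele in the genotype. For an
accession of ploidy $p \in \{2,3,4\}$ carrying $a$ copies of the alternate
allele Y and $p-a$ copies of the reference allele X, the signal is
determined by $a/p$. Across the three ploidy levels there are seven
distinct fractions --- $0, \tfrac14, \tfrac13, \tfrac12, \tfrac23,
\tfrac34, 1$ --- the *theoretical* classes 1--7. Assay resolution cannot
separate $\tfrac14$ from $\tfrac13$ nor $\tfrac23$ from $\tfrac34$, so at
most five *observed* classes remain. Observed classes 2 and 4 (unbalanced
heterozygotes) cannot be produced by a diploid and are flagged
*polyploid-like*:

```{r}
fluorescence_class_table()
```

Homozygotes of all ploidies collapse into classes 1 and 5; the balanced
heterozygotes 1:1 and 2:2 share class 3. `dosage_to_signal()` is the
vectorised map, `theoretical_classes()` / `merge_observed_classes()`
expose the enumeration for any maximum ploidy.

Dosage strings throughout the package are written `alt:ref` (so `1:2` is
a triploid with one alternate copy), matching the class table above.
Allele labels are assay-defined: X is the reference allele of the assay
design, with no strand flipping --- how the assay strand relates to a VCF
reference strand is panel metadata the model deliberately does not guess.

## Ploidy inference from the polyploid-like ratio

For accession $i$, let $R_i$ be the fraction of its heterozygous calls
(observed classes 2, 3, 4) that are polyploid-like (classes 2, 4).
Under the class model:

* a diploid has no true polyploid-like calls, so $R \approx \varepsilon_2$,
  the rate at which balanced heterozygotes are miscalled unbalanced;
* a triploid's heterozygotes are *all* unbalanced, so
  $R \approx 1 - \varepsilon_3$;
* a tetraploid sits in between, because its balanced 2:2 genotypes are
  genuinely not polyploid-like. At allele frequency $q$ the unbalanced
  fraction among tetraploid heterozygotes is
  $(4p^3q + 4pq^3)/(4p^3q + 6p^2q^2 + 4pq^3)$, which is $4/7 \approx 0.57$
  at $q = \tfrac12$ and rises toward 1 at rarer alleles; averaged over a
  realistic frequency spectrum it lands near 0.65--0.70.

`classify_ploidy()` applies two thresholds: $R < t_{low}$ is diploid,
$t_{low} \le R < t_{high}$ tetraploid, $R \ge t_{high}$ triploid. The
defaults $(0.35, 0.70)$ separate the theoretical expectations
($\sim\varepsilon_2$, $\sim 0.57$ at intermediate frequency,
$\sim 1-\varepsilon_3$); both are arguments, because the right cut
depends on the panel's allele-frequency spectrum --- the known weakness
of the statistic is triploid/tetraploid confusion when the panel is
rich in rare alleles, which pushes the tetraploid distribution up
against $t_{high}$. Accessions with fewer than `min_het_calls = 10`
heterozygous calls are reported uncallable rather than guessed: with $n$
informative calls the binomial standard error of $R$ is
$\sqrt{R(1-R)/n}$, and below ten calls that error spans the decision
boundaries. A model-based alternative (a three-component beta mixture
over $R$) was deliberately left out of the default path for
transparency; the report tibble returned by `polyploid_like_ratio()`
carries everything such an extension needs.

`assign_unknowns()` fills in only accessions of unknown declared ploidy
and never overwrites a declared value; a declared-vs-inferred
disagreement is flagged as a conflict (a curation signal, not an error).

## Duplicate detection and redundancy groups

Two (dis)similarity measures serve different jobs:

* **Presence/absence** compares any two accessions regardless of ploidy.
  Each call contributes its allele set (class 1 $\to$ {X}, classes 2--4
  $\to$ {X,Y}, class 5 $\to$ {Y}); per co-called locus the overlap is the
  Jaccard index (a heterozygote against a homozygote scores $1/2$), and
  the pair similarity is the mean over loci. The Dice variant
  (score $2/3$) is available behind the `index` switch; "fraction of
  shared alleles" does not pin down one index, so the choice is exposed.
* **Allelic dosage** refines comparison within one ploidy level after
  recoding observed classes to alternate-allele dosage codes. The
  recoding absorbs the known confusions: a diploid call scored
  polyploid-like can only be the 1:1 heterozygote (code 1); a triploid
  call scored balanced is one of the two unbalanced dosages and is coded
  1.5 --- the midpoint of the compatible codes $\{1, 2\}$, so that
  similarity and mismatch arithmetic with a 1.5 code equals averaging
  over the two dosages it may stand for. Tetraploid codes 0--4 need no
  correction. The per-locus shared-allele fraction for ploidy $p$ is
  $[\min(d_A, d_B) + \min(p - d_A, p - d_B)]/p$.

Duplicates: accessions of equal ploidy whose summed dosage difference
over co-called loci is at most `max_mismatch = 1` --- one allele, the
footprint of a single somatic mutation in a clonally propagated crop ---
are linked, and *redundancy groups* are the connected components of that
graph. Transitive closure is the only order-independent reading of
"grouping", and it is what makes a clone family cohere: two derived
clones may differ at two loci yet both sit one mutation from their
founder. Cross-ploidy pairs are never linked (a hard rule), pairs with
no co-called locus contribute no link, and missing loci are excluded
from the mismatch sum.

The mismatch rule presumes confident dosage calls. Under the triploid
balanced-miscall rate of the emulated assay ($\varepsilon_3 = 0.17$),
each miscalled heterozygote shifts a code by 0.5, so clone families of
triploids fragment unless calls are curated first; the presence/absence
measure, which ignores dosage within the heterozygote classes, is the
robust screen in that situation. This is a real operating constraint of
dosage-based duplicate detection, not an implementation artifact.

Per-group allele-frequency profiles (`group_allele_frequencies()`) are
dosage-weighted means over co-called members, in $[0,1]$, and feed the
two collection-level analyses.

## Gene pools: Ward clustering with multiscale-bootstrap AU support

Group profiles are clustered with Ward's minimum-variance linkage in the
`ward.D2` convention (squared-distance update on unsquared Euclidean
input). Support for each internal node comes from multiscale bootstrap:
markers --- the only exchangeable axis of a frequency profile --- are
resampled with replacement at relative sizes $r \in \{0.5, 0.6, \ldots,
1.4\}$ (ten scales), the tree is rebuilt, and $BP(r)$ is the fraction of
resampled trees containing the node's exact leaf set. Writing
$z(\sigma) = \Phi^{-1}(1 - BP)$ with $\sigma = \sqrt{\lceil rL \rceil / L}$
(the variance-scaling convention of the multiscale-bootstrap literature:
$\sigma^2$ is resample size over original size), the model
$z = v\sigma + c/\sigma$ is fitted by weighted least squares with the
delta-method Fisher weights $B\,\phi(z)^2 / (BP(1-BP))$; then

$$AU = 1 - \Phi(v - c), \qquad BP_{\sigma=1} = 1 - \Phi(v + c),$$

with $v$ the signed distance and $c$ the curvature of the node's region
boundary. Degenerate curves (fewer than three scales with
$0 < BP < 1$) skip the fit: $AU$ is 1 when the BPs saturate at 1 and 0
when they sit at 0, with a flag --- common with 129 markers, where
well-separated nodes saturate.

Significant gene pools are the *maximal* (closest-to-root) nodes with
$AU \ge 0.95$ whose leaf sets are disjoint; nested significant nodes are
absorbed by their outermost ancestor, and leaves covered by no
significant node are reported unassigned. The root --- the trivial
cluster of all leaves, whose BP is identically 1 --- is excluded: under
a one-cluster null the root *is* the truth, and reporting it would say
nothing about grouping. Ties in the Ward merge order are resolved by
`stats::hclust`'s deterministic scan order, so a fixed seed gives
bit-identical BP tables.

## The kinship network

Between-group kinship is profile similarity $1 - \overline{|\Delta
f|}$ over co-called markers, chosen so that groups of different ploidy
remain comparable. Significance comes from genotype permutations: each
permutation independently shuffles, per marker, the frequency values
across groups, breaking group identity while preserving every marker's
frequency spectrum (the groups, not the accessions, are the network's
objects --- permuting accessions before grouping is the documented
alternative, not the default). One-sided empirical p-values use the
add-one estimator $p = (1 + \#\{\text{null} \ge \text{obs}\}) /
(B_{perm} + 1)$, never exactly zero; pairs with $p < 0.05$ become edges.
No multiple-testing correction is applied --- the single threshold is the
method's convention --- so the network is a screening device, and the
per-pair type-I rate (checked by simulation to sit at $\alpha$) should
be kept in mind when reading dense networks.

## Panel design

The upstream marker-selection stage is reimplemented natively from a
multi-sample VCF:

* per-genotype read depth below 8 masks the call; sites are kept only if
  biallelic SNPs, minor-allele frequency $\ge 0.1$ among called
  genotypes (alleles counted at full dosage weight --- "max-missing
  0.60" follows the convention *keep sites with at least 60% of
  genotypes called*, stated explicitly because the double negative is a
  classic trap);
* accessions with more than 70% missing genotypes are dropped;
* thinning (last, after all content filters) keeps no two sites within
  64 bp on one chromosome, greedily in coordinate order, so the first
  site of a close run survives;
* flanking sequences of 60 bp either side are extracted for assay
  design, truncated (and flagged) at contig ends, as `LEFT[REF/ALT]RIGHT`
  strings;
* `k = 192` representative SNPs are chosen by k-means on a single
  cumulative genome coordinate (position plus the summed lengths of
  preceding chromosomes, chromosome order fixed by the length table).
  One-dimensional k-means is solved *exactly* by dynamic programming
  over the sorted coordinates (optimal 1-D clusters are contiguous), so
  the selection is deterministic --- no seed, no Lloyd restarts --- and
  the representative of each cluster is the site nearest its centroid,
  ties to the lower coordinate.

The panel-design stage requires genome positions for all candidate
sites; unmapped candidates are out of its contract.

## The synthetic-data generator

No genotype data are distributed with the emulated study, so every
pipeline stage is exercised on `simulate_panel()` output whose defaults
*are* the study conditions: 129 biallelic markers with base
alternate-allele frequency uniform on (0.05, 0.5); 141 accessions (96
diploid, 36 triploid, 9 tetraploid) in 43 clonal lineages with sizes
1--24 (largest families 24, 18, 14); five gene pools; diploid
balanced-het miscall rate $\varepsilon_2 = 0.09$ and triploid
unbalanced-het miscall rate $\varepsilon_3 = 0.17$ (one minus the
respective reported correct-call ratios, so the emulated panel
reproduces them by construction); 0.5% missing calls. The
between-accession spread of $R$ ($\pm 0.05$) arises naturally from
binomial counting over roughly 40--70 heterozygous calls per accession;
no extra dispersion knob exists.

Frequencies follow a three-level hierarchy. Each pool deviates from the
collection base frequency on its own disjoint block of signature
markers; lineage founder frequencies then drift from their pool by
Balding--Nichols beta sampling with `lineage_fst = 0.05`; founder
dosages are binomial; clones copy their founder and apply at most
`somatic_budget = 1` random $\pm 1$ dosage change (the somaclonal
variant model); the observation layer applies the signal-class map, the
miscall flips and missingness, fully seeded.

Two generator choices deserve explanation because they were forced by an
interaction between Ward linkage and bootstrap support:

* **Star pools with flattened merge costs.** The five pools are a
  planted partition with *no* hierarchical relationships. Per-pool
  deviation norms are solved (with a small least-squares step,
  `pool_merge_cost = 47`) so that the Ward merge cost of every pool pair
  is as equal as possible, subject to a floor (`pool_min_drift = 5.5`)
  that keeps singleton-rich pools coherent against the binomial noise of
  single-accession profiles. With unequal costs (e.g. naive independent
  drift per pool), the arrangement *above* the pools is stable under
  marker resampling --- Ward's size factors do not resample --- and
  supra-pool nodes earn $AU \approx 1$, so the maximal-node rule reports
  two superclusters instead of five pools. Flattened costs make every
  supra-pool merge a contest that marker resampling reshuffles, which is
  exactly the statement "these five pools have no higher-order
  structure".
* **Near-equal pool sizes.** For the same reason, pool lineage-counts
  are balanced (9/8/9/9/8): a single dominant pool would merge last
  deterministically and hand its complement node permanent support. The
  pools have mixed ploidy composition (A triploid-dominated,
  B tetraploid-dominated, C carrying the largest clone families).

What the generator does *not* emulate --- and hence what green tests do
not certify about real data: linkage disequilibrium between markers
(profiles here are independent across loci; the bootstrap's
exchangeability assumption is exactly true in simulation and only
approximate on a real panel), assay failure and locus dropout,
fluorescence-intensity structure below the class level, admixed
accessions between pools, and real pools' unequal sizes and partial
hierarchy --- on real collections the gene-pool count is a data outcome,
not a target.

## Numerical and testing choices

* Class arithmetic uses exact integer fractions ($12a/p$), never
  floating comparisons.
* Missing calls are `NA` end to end, excluded from every denominator;
  no numeric sentinel exists in the data model.
* Empirical p-values are add-one; AU fits guard degenerate BP curves;
  bootstrap and permutation stages take explicit seeds and the pipeline
  derives per-stage seeds from one global seed by fixed offsets.
* Test problem sizes: unit oracles run on panels up to $10 \times 10$
  against brute-force per-locus recomputation (tolerance $10^{-12}$);
  the exact k-means is checked against full set-partition enumeration at
  $n \le 8$; bootstrap calibration uses 1,000 replicates over 20 null
  data sets and network calibration 1,000 permutations over 50
  replicate panels; end-to-end recovery runs the full 141 x 129
  geometry with up to 2,000 bootstrap replicates. These sizes are the
  package's chosen verification scale; the stages themselves default to
  the analysis-scale settings (10,000 boots, 1,000 permutations).

## Known limitations

* The dosage mismatch rule is sensitive to heterozygote miscalls (0.5
  mismatch per confounded triploid call); curate calls or fall back to
  presence/absence before trusting duplicate groups on noisy panels.
* $R$-based ploidy inference degrades for panels dominated by rare
  alleles (tetraploids drift toward the triploid threshold) and cannot
  call accessions with very few heterozygous loci.
* AU p-values are approximately unbiased, not exact; with 129 markers
  the saturated-node shortcut is common and such nodes carry no
  curvature information.
* The network applies no multiple-testing correction by design.
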