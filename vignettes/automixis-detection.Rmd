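---
title: "Detecting automixis mechanisms from mother-offspring genotype trios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting automixis mechanisms from mother-offspring genotype trios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(automixr)
```

## The problem

Facultative parthenogenesis (FP) — asexual reproduction by a normally
sexual species — is regularly reported in snakes, lizards, sharks and
birds. In nearly all vertebrate cases diploidy is restored by
*automixis*: meiosis proceeds, and two of the mother's own meiotic
products fuse (or one duplicates). The automictic mechanisms leave
distinct genomic fingerprints in the offspring:

* **Terminal fusion (TF)** — the egg fuses with its *second polar body*,
  the sister-chromatid product of meiosis II. The fused products are
  identical from the centromere to the first crossover, so maternal
  heterozygosity survives only *distal* to crossovers, toward the
  telomeres. Offspring heterozygosity is strongly reduced but non-zero.
* **Central fusion (CF)** — the fusion involves a *first polar body*
  product (a non-sister chromatid). Heterozygosity is retained proximal
  to crossovers and overall remains comparable to the mother.
* **Gametic duplication (GD)** — a single gamete's genome is duplicated:
  the offspring is homozygous at every locus.
* **Apomixis** — no meiotic reduction; the offspring is a clone of the
  mother.

Discriminating TF from GD historically failed because a handful of
microsatellites is unlikely to land in the telomeric windows where TF
retains heterozygosity. With thousands of SNP markers from
reduced-representation sequencing (ddRAD), the mechanisms separate
cleanly: TF offspring show low-but-identifiable heterozygosity, near-1
relatedness to the mother, and retained-heterozygosity positions that
cluster in the same genomic regions across siblings.

This package implements that inference end to end for a
mother-plus-offspring trio: the site filter cascade, individual
heterozygosity and pairwise relatedness with locus bootstraps, fate
classification of maternal heterozygous loci, an exact binomial test for
inheritance bias, a permutation test for shared retained heterozygosity,
a GC-content comparison around retained versus lost heterozygosity, and
a transparent rule-based mechanism call. A chromatid-level meiosis
simulator provides ground-truth datasets so every statistic has a
known-answer test.

## The statistics

For one sample over $L$ genotyped biallelic loci, **observed
heterozygosity** is $OH = L_{het}/L$. **Homozygosity by loci** weights
each locus by its information content: with sample allele frequencies
$p, q$ and expected heterozygosity $E = 1 - p^2 - q^2$,

$$HL = \frac{\sum_{h \in \text{hom}} E_h}{\sum_{h \in \text{hom}} E_h + \sum_{j \in \text{het}} E_j},$$

so uninformative (monomorphic, $E = 0$) loci carry no weight. Pairwise
relatedness is summarized by the shared-alleles index $B_{xy}$ (per-locus
score 1 for identical genotypes, 0.5 for one shared allele, 0 for none)
and the genotype-sharing index $M_{xy}$ (shared alleles under the best
pairing, divided by two). On biallelic data the two coincide locus by
locus — the package computes them by independent routes and the test
suite checks the equality by enumeration. A parent and its sexually
produced offspring always share at least one allele per locus, so values
near 1 (rather than near the parent-offspring range) indicate a
parthenogen. Uncertainty for all four metrics comes from bootstrapping
loci (not individuals — the design is a single family), resampling to
the original locus count, 100 replicates by default.

Among maternal-heterozygous loci, each offspring genotype is classified
as 0/0, 0/1 (retained) or 1/1. Unlinked loci that lose heterozygosity
should fix either parental allele with probability one half, which the
package tests with the exact two-sided binomial test (summing all
outcomes whose point probability does not exceed the observed one).
Shared retention between two offspring is measured by the Jaccard index
$J(A,B) = |A \cap B| / |A \cup B|$ over retained-locus sets, compared
against a permutation null that redraws each offspring's retained set
uniformly from the maternal heterozygous loci, preserving both set
sizes. This is the minimal null that respects the margins; because the
intersection size under it is hypergeometric, the test suite checks the
permutation null mean against the exact expectation
$\sum_k P(k)\, k/(|A|+|B|-k)$. The empirical p-value uses the add-one
estimator $(1 + \#\{J_{null} \ge J_{obs}\})/(1 + n_{perm})$ so it is
never exactly zero. The package also reports
$|A \cap B| / \min(|A|,|B|)$, since "percent shared retention" in the
literature is sometimes this quantity rather than the Jaccard index.

## The filter cascade

`apply_site_filters()` applies, in order: (1) indels removed; (2)
genotype calls with per-sample depth < 5 set missing; (3) SNPs within
3 bp of an input indel removed (indel clusters within 10 bp are
flagged); (4) site quality < Phred 30 removed; (5) GATK-style INFO hard
filters (`QD < 2`, `FS > 60`, `MQ < 40`, `MQRankSum < -12.5`,
`ReadPosRankSum < -8`) applied to whichever keys the input carries,
skipping absent keys with a logged warning; (6) total-depth outliers
removed; (7) non-biallelic records removed; and finally complete-case
filtering across the trio. The cascade starts from genotypes, not reads:
mapping and variant calling are upstream of this package.

Two conventions are worth stating. Thinning windows
(`thin_by_window()`, 50 kb default) are anchored at coordinate 0 —
the simplest reproducible choice when only "one variant per 50 kb
region" is specified. And the total-depth bounds default to
$[0.5, 2] \times$ the mean total depth *of the incoming dataset* rather
than fixed counts; absolute counts only generalize across datasets as
multiples of the mean. A consequence is that re-running the cascade on
its own output can re-derive slightly different bounds (the outliers are
gone, so the mean moved); the resolved bounds are therefore recorded in
the filter log and in `attr(, "resolved_config")`, and re-applying the
cascade *with its resolved configuration* is exactly the identity —
which is what the test suite asserts. Fixed bounds can always be passed
explicitly.

`derive_rad_loci()` reconstructs the RAD locus footprint from per-base
depth: a base passes when depth $\ge 5$ in every sample at quality
$\ge 30$; passing runs separated by $\le 10$ bp are merged (gap included
in the span); merged loci shorter than 100 bp are dropped. The merge is
`IRanges::reduce()` with `min.gapwidth = max_gap + 1`; the tests compare
it against a per-base brute-force scan, including the 10/11-bp gap and
99/100-bp length boundaries. The package treats all chromosomes
identically — snake Z-linked loci in ZZ male offspring are diploid
anyway — but `filter_config(exclude_chroms = ...)` is available when a
Z or W scaffold list is known.

## The simulator

`simulate_trio()` models meiosis explicitly at the chromatid level.
Each chromosome is replicated into four chromatids (two sister pairs);
a crossover count is drawn (one obligate crossover per chromosome by
default, plus a Poisson number of extras, default mean 0); each
crossover picks a uniform position and one chromatid per homolog
uniformly, and exchanges the material *distal* to the breakpoint —
away from the centromere on the breakpoint's arm. One homolog's sister
pair, chosen uniformly, becomes the egg lineage (egg + second polar
body), the other the first polar body: the standard meiosis-II /
meiosis-I identities. Crossover interference is not modeled — positions
are independent, the simplest model that produces the right tract
geometry — and sex chromosomes are not simulated.

Offspring formation follows the mechanism definitions directly: TF =
egg + its sister; CF = egg + a uniform first-polar-body chromatid; GD =
egg doubled; apomixis = maternal genotypes copied; sexual = egg + an
unrelated haplotype with configurable allele frequency (0.5 by
default, so every marker is informative). Each non-sexual offspring
carries a ground-truth list of the intervals where its two chromatids
descend from different haplotypes — exactly the regions where
maternal heterozygosity survives — plus the crossover positions.
Useful consequences, all tested: under a single crossover, TF retains
heterozygosity exactly and only distal to the breakpoint (expected
fraction one half for a uniform crossover on a telocentric chromosome);
CF tracts always reach the centromere and cover the whole chromosome
half the time; GD offspring have $OH = 0$ exactly; apomicts have
$M_{xy} = 1$ exactly.

Default study conditions emulate a snake RADseq trio: 18 chromosomes,
20,562 markers, maternal heterozygous fraction $278/20562 \approx
0.0135$, telocentric chromosomes (centromere at 0, so "distal" means
larger coordinates), negative-binomial per-call depth with mean 17 per
sample (trio total near 50) and dispersion 5, and 2% genotype
missingness. Chromosome *length* is scaled to 1 Mb: every marker-level
statistic in the package depends on relative positions only, so the
scale affects nothing but the size of the emitted reference FASTA
(18 Mb rather than a 1.6 Gb genome). The reference sequence gets a
configurable GC background; setting `gc_distal` above `gc_content`
creates GC enrichment away from centromeres, which serves as the
positive control for the GC analysis below.

What the simulator deliberately does **not** emulate: genotyping error,
allele dropout, reference-allele call bias, linkage disequilibrium
beyond physical linkage, crossover interference, and population
structure in the sexual parent. Passing tests therefore demonstrate
correctness of the *inference machinery* under a clean generative
model, not robustness to every artifact of real RADseq data. One
concrete illustration: on clean simulated trios the mother's $HL$ is
exactly 0, because every locus that is polymorphic within the trio is
heterozygous in the mother — only genotyping error (or a sexual
father) can make a locus variable while the mother is homozygous. A
non-zero maternal $HL$ in real trio data is thus itself a signal of
residual genotyping noise.

## The mechanism call

`diagnose_mechanism()` is deliberately a transparent rule table, not a
model fit; the evidence payload and thresholds are always attached to
the verdict. Defaults: mother-offspring relatedness $\ge 0.95$ is
"clonal-scale"; within it, retained fraction $\le 0.5\%$ (or $\le 2$
loci) calls GD, offspring/mother OH ratio $\ge 0.8$ calls
CENTRAL_FUSION_LIKE (with a clone flag when $M_{xy} \ge 0.999$), and
anything between calls TF. Relatedness in $[0.55, 0.92]$ calls SEXUAL —
on all-marker data a parent and sexual offspring sit near 0.75, not the
textbook 0.5, because loci homozygous in both contribute full scores.
Anything else is INCONCLUSIVE. Two caveats are inherent, not bugs: a
true clone and a central-fusion parthenogen are only distinguishable by
tract geometry, not by genome-wide summaries, so apomicts surface as
CENTRAL_FUSION_LIKE with the clone flag; and a CF parthenogen whose OH
ratio falls below 0.8 (the default simulator produces about 0.75 under
one obligate crossover) is conservatively labeled TF — the classifier's
job is rejecting GD and sexual origin, and the threshold is a config
knob, not a constant.

## Numerical and design choices

* Genotypes are integer ALT-dosage codes (0/1/2/NA), so dosage
  arithmetic gives $M_{xy} = 1 - |d_x - d_y|/2$ directly.
* Crossover positions are continuous uniform draws, so breakpoints
  never tie with integer marker coordinates; marker lookups evaluate
  chromatid segments at the base midpoint.
* All randomized operations take explicit seeds and restore the
  caller's RNG state; `run_pipeline()` fans a single global seed into
  per-stage seeds by fixed offsets so stages are independently
  reproducible. Two runs with the same seed emit byte-identical VCFs
  and reports.
* The empirical p for permutation tests uses the add-one estimator;
  both a Mann-Whitney and a label-permutation p accompany the GC
  comparison because a claim of "statistically indistinguishable"
  fixes no particular test.
* Degenerate inputs error early with informative messages: all-missing
  call vectors, a mother with zero heterozygous loci, an empty fate
  table, zero informative loci for HL, unknown comparators, mismatched
  depth tracks.
* Problem sizes in the test suite are chosen to keep the full run at a
  few minutes: mechanism recovery uses 50 replicates per mechanism at
  5,000 markers; the terminal-fusion retention check uses 2,000
  simulated meioses on one chromosome; null calibration of the GC
  comparison uses 100 seeds at 99 label shuffles each.

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(
  sim = sim_config(),            # study-scale defaults, two TF siblings
  mechanisms = c("TF", "TF"),
  thin_window_bp = NULL,         # simulated markers are already unlinked
  n_boot = 100, n_perm = 100,
  seed = 1, out_dir = "results_run"
)
report <- run_pipeline(cfg)
report$fate_table
report$mechanism
```

The report contains the per-sample OH/HL table with bootstrap SDs, the
relatedness matrix ($B_{xy}$ above the diagonal, $M_{xy}$ below), the
per-offspring fate tally with exact binomial p-values, the Jaccard
observed/null/p summary, the GC comparison, and one mechanism call per
offspring, together with the full configuration echo — every number in
it is recomputable from the config and seed alone.

## Known limitations

* The classifier cannot separate apomixis from central fusion without
  tract-level data; it flags clones instead.
* HL requires allele frequencies; with a three-sample family the only
  internal choice is the analyzed samples themselves, which compresses
  HL toward 0 for the mother on error-free data. An external frequency
  table can be supplied.
* The GC comparison has realistic power only when retained and lost
  classes hold dozens of loci each; with very few retained loci the
  permutation p is honest but uninformative.
* OH depends on its denominator (all genotyped loci). Published OH
  values whose denominators are ambiguous (all loci vs. variable loci)
  can differ from this package's convention by a constant factor; the
  filter log records every count needed to convert.
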