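---
title: "Population analysis of insertionally polymorphic ERVs"
author: "ervpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population analysis of insertionally polymorphic ERVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressPackageStartupMessages(library(ervpop))
```

## The problem

Endogenous retroviruses (ERVs) are retroviral integrations inherited through
the host germline. Young integrations segregate as insertion polymorphisms:
a locus may be occupied in some individuals and empty in others, and the
occupancy frequency varies among populations and species. Short-read cohorts
expose these loci indirectly, through two complementary kinds of caller
output:

* **non-assembly loci** — insertions absent from the reference assembly,
  reported by a discordant-read caller at the empty pre-integration site;
* **assembly loci** — ERVs present in the reference but deleted on some
  sampled haplotypes, reported as deletion calls (a read-depth dialect with
  two e-value-like scores, and a genotyped split-read dialect) that overlap
  ERV-similarity blocks along the reference.

`ervpop` turns per-individual call tables of both kinds into a unified locus
frame, a locus-by-individual presence matrix, per-species occupancy
frequencies, abundance summaries, and downstream screens, for a cohort
structured as species split across island populations.

## The pipeline

1. **Filtering.** Insertion calls pass a *stringent* cascade
   (support reads $\ge 5$, filter level $\ge 8$, genotype quality in
   $[10, 200]$, both soft-clip supports $\ge 2$) used to *define* loci, and a
   *relaxed* cascade (1 read, filter level $\ge 5$) used to *count*
   identifications per locus. Read-depth deletions pass
   $\mathrm{eval1} \le 0.05$, $\mathrm{eval2} \le 0.05$, length
   $\le 20\,\mathrm{kb}$ (relaxed: both evals $\le 1$, no length cap — the
   relaxed pass deliberately restates only the score thresholds); split-read
   deletions pass a 90 bp–20 kb length band with $\ge 2$ supporting reads in
   both modes. All printed thresholds are treated as inclusive, since none
   are stated with strictness qualifiers.
2. **Locus construction.** Each stringent insertion position is extended by
   50 bp in both directions (a 101 bp window) and overlapping windows are
   reduced transitively — `GenomicRanges::reduce()` with
   `min.gapwidth = 0L`, so intervals sharing at least one base merge while
   merely adjacent ones do not. Deletions annotated with the family of their
   maximally overlapping similarity block are reduced the same way, per
   dialect, with no extension. The unified frame concatenates both sources;
   locus identifiers follow the `ERV-<clade>.<family>.<serial>` style and
   are cosmetic.
3. **Presence.** A non-assembly entry counts relaxed calls whose extended
   window overlaps the locus. An assembly entry starts at 1 (the reference
   carries the ERV) and becomes 0 when a passing deletion covers the locus —
   any read-depth deletion, or a split-read record genotyped as a homozygous
   deletion. A heterozygous deletion leaves the individual a carrier: one
   haplotype still holds the ERV, and presence is an individual-level
   indicator, not an allele count.
4. **Frequencies and calibration.** Group frequency is the detected fraction
   of the group's individuals. Loci detected at least once in *every*
   in-scope group are ancestral-fixation candidates; because such loci are
   expected homozygous everywhere, their expected detection frequency is
   1.0 and the shortfall of the observed mean estimates the homozygous
   false-negative rate, $\widehat{FN} = 1 - \bar f_\mathrm{fixed}$. The
   default scope is species plus outgroups, excluding hybrid groups: a
   hybrid bucket is not a species-age stratum, while outgroups sharing a
   locus strengthen the ancestrality argument.
5. **Abundance and MIR.** Relative abundance of family $f$ in individual
   $i$ is $r_{if} = n_{if} / \sum_g n_{ig}$ over identification counts.
   The median identification ratio for family $f$ in group $G$ is
   $\mathrm{MIR}_{fG} = \mathrm{med}_{i \in G}(r_{if}) /
   \mathrm{med}_{i}(r_{if})$ with the all-sample pool as denominator; the
   modified (island) variant divides an island population's median by its
   *species* median, so a single-island species is exactly 1. Ratios are
   undefined (missing) where the reference median is zero. Medians of
   even-sized groups use the midpoint convention of `stats::median`.
6. **Sharing, density, screens.** Loci are classed `all_species` /
   `multi_species` / `private` by the number of groups with non-zero
   frequency. Chromosomal density is loci per Mbp using locus midpoints,
   with a binned positional profile and an end-enrichment ratio (mean
   density in the two terminal windows of fractional width 0.1 over the
   interior mean). The differentiated-region screen intersects loci with
   region intervals by any one-base overlap and reports loci with
   $|\Delta| = |f_A - f_B| \ge 0.4$ for an ordered species pair, sorted by
   $\Delta$; an optional mid-species frequency is displayed but never
   filtered on — intermediate status is an observation, not a criterion.
   The 0.4 default reproduces a published 13-locus selection whose smallest
   printed contrast is 0.42, and is exposed as configuration because the
   original cutoff is not stated.

Group comparisons use Welch's two-sample $t$ (Satterthwaite degrees of
freedom, two-sided) and classical one-way ANOVA, delegated to
`stats::t.test()` and `stats::oneway.test(var.equal = TRUE)`; the test suite
cross-checks both against direct formula evaluation. When the pooled data
are constant the ANOVA ratio is $0/0$; the package defines this degenerate
case as $F = 0$, $p = 1$.

## The synthetic cohort generator

Real inputs of this kind derive from hundreds of resequenced genomes, so the
generator is a first-class module that emulates the study conditions and
gives every downstream stage a known truth.

* **Cohort structure.** `nSpecies` species × `islandsPerSpecies` islands ×
  `individualsPerPopulation` individuals; per-individual mean coverage
  uniform on 6–49×, matching the coverage span of the emulated cohorts.
* **Truth loci.** `nFixedLoci` ancestral loci homozygous in everyone, plus
  `nPolymorphicLoci` post-speciation loci. Each polymorphic locus is
  assigned to a proper subset of species (post-speciation insertions never
  occupy all species; the subset size is geometric, favouring private and
  few-species loci, which mirrors the observed dominance of narrowly shared
  loci). Carrier species get a base insertion frequency uniform on
  0.1–0.9, jittered by ±0.15 per island to create island structure, and
  genotypes are drawn under Hardy–Weinberg proportions — zygosity is
  simulated even though downstream analysis uses presence only, because the
  detection model differs by zygosity. Optional per-species family
  multipliers bias carrier assignment to model lineage-restricted expansion
  bursts. Positions are drawn on a 1 kb grid with ±400 bp jitter (keeping
  distinct truth loci from fusing during the 50 bp-extension merge) with
  optional extra mass in the terminal 10% of each chromosome.
* **Detection model.** Zygosity 0 is never called. Homozygous loci are
  called with constant probability $1 - \texttt{homMissProb}$ (default
  0.92): the fixed-locus calibration that anchors this rate pools
  individuals across all coverages, so the simplest model consistent with a
  single calibrated number is coverage-free. Heterozygous sensitivity rises
  linearly from 0.45 at 4× (a 55% false-negative rate) to 1.0 at 30×, is
  clamped to $[0,1]$, and is constant above saturation; below 4× the same
  line is extrapolated and clamped rather than inventing an unobserved
  regime. Detection events are independent Bernoulli per locus–individual
  pair; no correlation structure is imposed because none is documented.
* **Call emission.** Detected non-assembly carriers emit one insertion call
  with ±10 bp positional jitter; the call's filter fields pass the stringent
  cascade with probability `stringentPassProb` (default 0.9) and always
  pass the relaxed one. A fraction of polymorphic loci
  (default $698/26\,964 \approx 2.6\%$, split $207:491$ between the
  read-depth and split-read dialects) is represented assembly-side instead:
  non-carriers emit deletion calls (heterozygous carriers emit
  genotype-1 split-read records), and each assembly locus has a matching
  similarity block. Deletion emission is noise-free — the false-negative
  model is calibrated for insertion calls only, and no analogous rate is
  documented for deletion callers. Assembly representation is restricted to
  polymorphic loci by construction: a reference ERV present in every
  individual produces no deletion call and could never be discovered as an
  assembly locus.

What the generator does **not** emulate: read-level artefacts (no
FASTQ/BAM), mapping ambiguity near repeats, correlated caller failures,
false-positive calls, solo-LTR versus full-length provirus states, and
drift/selection dynamics over generations. Passing tests therefore
demonstrate the correctness of the pipeline's arithmetic and its parameter
recovery under the stated detection model, not robustness to every artefact
of real short-read data.

## Numerical and design choices

* Internal coordinates are 1-based closed (`GRanges` convention); BED I/O is
  0-based half-open via `rtracklayer`, and TSV readers accept a declared
  0-based dialect. Round trips are identities.
* Extension of a point call is a symmetric closed window of 101 bp;
  "overlap" always means at least one shared base, so touching windows
  remain distinct loci.
* Majority-family annotation breaks ties by earliest constituent call
  position, then lexicographically; similarity-block assignment breaks
  overlap ties by lower block start, then family name — all outputs are
  deterministic.
* Numeric output uses dot decimals; the frequency-table reader also accepts
  comma decimals so published tables can be ingested byte-faithfully.
* Relative abundance uses identification *counts*; a binary mode exists for
  sensitivity analysis. Zero-identification individuals yield missing rows
  with a warning rather than silent zeros.
* The coverage regression defaults to the per-individual detection rate at
  calibrated fixed loci (the interpretable response); per-individual total
  call counts are available as an alternative response.
* Relaxed calls falling outside every stringent-defined locus are discarded,
  mirroring the locus-frame logic of the emulated pipeline.

## Problem sizes

The suite's simulation checks run at sizes chosen to keep Monte-Carlo error
well inside the asserted tolerances: the calibration-recovery check uses 5
species × 300 individuals × 1800 loci (binomial standard error of the
fixed-locus mean ≈ 0.001, an order of magnitude under the ±0.01 assertion),
and the heterozygous-sensitivity check uses about 17,000 heterozygous
carrier–locus pairs at fixed 4× coverage (s.e. ≈ 0.4 percentage points
against a ±5 point assertion). The brute-force interval-union oracle is
compared on 1,000 random call sets of up to 10 calls.

## Worked example

```{r example}
p <- SimulationParams(nSpecies = 3L, islandsPerSpecies = 2L,
                      individualsPerPopulation = 5L,
                      nFixedLoci = 50L, nPolymorphicLoci = 200L,
                      rngSeed = 42L)
sim <- simulateCohort(p)
tb <- emitCallTables(sim)

insS <- filterInsertionsStringent(tb$insertions)
insR <- filterInsertionsRelaxed(tb$insertions)
nonAsm <- mergeInsertionLoci(insS, chromLengths = p@chromLengths)
dels <- rbind(tb$cnv_deletions, tb$sv_deletions)
dels$truth_locus_id <- NULL
asm <- buildAssemblyLoci(annotateWithSimilarity(
    filterDeletions(dels, "stringent"), tb$similarity_blocks))
loci <- unifyLocusFrame(nonAsm, asm)
pres <- genotypePresence(loci, insR,
                         annotateWithSimilarity(
                             filterDeletions(dels, "relaxed"),
                             tb$similarity_blocks),
                         tb$samples)
freq <- speciesFrequency(pres)
fixedLocusCalibration(freq, tb$samples)
classifySharing(freq)$summary
```

## Known limitations

* Frequencies are individual-level detection frequencies; allele
  frequencies and locus ages are out of reach without zygosity-resolved
  calls.
* The calibration assumes candidate fixed loci are truly ancestral; a locus
  segregating at high frequency in every group inflates the estimated
  false-negative rate. In simulations the generator's post-speciation
  design eliminates this contamination; on real data the estimate is an
  upper bound.
* The region screen is a descriptive contrast, not a selection test; no
  significance is attached to $\Delta$.
* Hybrid groups are carried through frequency and abundance tables but are
  excluded from fixation scope by default.
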