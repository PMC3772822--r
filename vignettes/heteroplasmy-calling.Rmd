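---
title: "Calling mitochondrial heteroplasmy from deep-sequencing pileups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling mitochondrial heteroplasmy from deep-sequencing pileups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mthet)
```

## The problem

Mitochondrial genomes exist in many copies per individual, and those copies
need not be identical: a site where a minor allele segregates within one
individual is *heteroplasmic*. With deep amplicon sequencing (thousands of
reads per position) heteroplasmy shows up in the pileup as a non-consensus
base carried by a small but consistent fraction of reads. The difficulty is
that sequencing error produces exactly the same signature at low frequency,
so heteroplasmy calling is a signal/noise separation problem governed by the
per-base error rate of the platform and the read depth.

`mthet` implements this separation for small, deeply sequenced genomes. The
package was designed around two mitochondrial architectures: the fragmented
genome of human lice (*Pediculus*), whose ~15 kb of coding sequence is
spread over 20 circular minichromosomes of 3–4 kb, and the conventional
single-chromosome (~16 kb circular) mitochondrial genome of ticks.

## The calling model

Calls are made per sample against the sample's own **consensus** (the
majority base of each pileup column), which bounds the minor-allele
frequency at 50%. Four filters are applied in order; a site must survive
all of them to count as heteroplasmic.

1. **Frequency threshold.** A non-consensus base with count $k$ at depth
   $n$ is a candidate only when $k/n$ is *strictly* greater than
   `min_freq` (default 1.5%, i.e. three times the assumed error rate;
   sites at exactly 1.5% are excluded). When several alternate bases
   qualify at one position the site is represented once, by the
   highest-count alternate, and flagged multi-allelic.

2. **Binomial false-positive probability** $P_f$. Under a uniform per-base
   error rate $p$ (default 0.5%, typical of Illumina-class platforms), the
   probability that error alone explains the observation is scored as

   $$P_f = \binom{n}{k} p^k (1-p)^{n-k},$$

   the binomial point mass at $k$, evaluated in log space
   (`pf_mode = "pmf"`, the default). The statistically conventional
   alternative — the exceedance probability $P(X \ge k)$ under
   $X \sim \mathrm{Bin}(n, p)$ — is available as `pf_mode = "tail"`. The
   point mass is the default because it is the published form of this
   screening statistic; the tail probability is strictly larger, so the
   default is the *less* conservative of the two at fixed threshold, and
   users who want an orthodox hypothesis test should switch modes.
   Candidates with $P_f \ge$ `pf_max` (1%) fail.

3. **Storey q-values** $Q_f$. $P_f$ values are converted to q-values with
   the step-up rule over the sample's candidate set: with order statistics
   $p_{(1)} \le \dots \le p_{(m)}$,

   $$q_{(i)} = \min_{j \ge i} \; \frac{\pi_0 \, m \, p_{(j)}}{j}.$$

   $\pi_0$, the assumed proportion of true nulls, defaults to the fixed
   value 0.05 — appropriate when the candidate list is already heavily
   enriched for real variants by the frequency screen — and can instead be
   estimated from the candidate p-values with the Storey smoother
   (`estimate_pi0 = TRUE`). Because q-values scale linearly in $\pi_0$,
   the fixed default makes $Q_f$ a simple monotone transform of $P_f$;
   it matters only where calibration against the 0.1% threshold
   (`qf_max`) is tight. Q-values are computed per sample; pooling across
   samples changes $m$ and is deliberately not the default, since samples
   are sequenced as separate libraries.

4. **Sequencing-error hotspots.** Two rules borrowed from studies of
   Illumina error structure: (a) a call immediately adjacent to a
   homopolymer run of four or more identical reference bases is excluded —
   the run is checked on *both* sides of the site because reads come from
   both orientations, with modular wraparound on circular chromosomes and
   truncated (non-qualifying) flanks at linear chromosome ends; (b) both
   members of a pair of called sites at consecutive positions in the same
   sample are excluded. Hotspot exclusion is applied after the
   significance filters, so the attrition report attributes each removal
   to the first filter that failed.

### Minimum informative depth

The frequency and $P_f$ thresholds interact with depth: at fixed
frequency threshold $f$, the smallest $k = \lceil f n \rceil$ grows with
$n$ while its null probability shrinks, so there is a minimum coverage
below which no call at frequency $f$ can reach $P_f <$ 1%. That minimum
drops as $f$ rises — at $f = 5\%$ a few dozen reads suffice, at $f = 1\%$
several hundred are needed. The test suite asserts this monotonicity; at
the study-like depths the package targets (~1,700–6,000×) all thresholds
from 1% upward are comfortably identifiable.

## Annotation

Passing calls are located in a gene annotation table (1-based inclusive
coordinates; origin-spanning genes on circular chromosomes use modular
arithmetic). For protein-coding genes the affected codon is read on the
coding strand — minus-strand genes reverse-complement — the variant base is
substituted at its codon position, and both codons are translated with the
gene's translation table (default: the invertebrate mitochondrial code,
table 5, in which `TGA` = Trp, `AGA`/`AGG` = Ser, `ATA` = Met). A call is
synonymous iff the amino acid is unchanged. Nonsynonymous calls are further
classified by which of three property dimensions flip: hydropathy
(hydrophobic = A,V,L,I,M,F,W,C,Y), polarity (polar =
S,T,N,Q,Y,C,H,K,R,D,E) and charge (+ = K,R,H; − = D,E). These default sets
are one conventional choice among several in the literature; they are a
configurable input (`read_aa_properties()`), not a claim about the single
correct classification. Changes involving a stop codon are recorded as
nonsense and excluded from property tallies; codons containing `N`
translate to the unknown sentinel `X` and are excluded from
synonymous/nonsynonymous totals. tRNA calls report whether they hit the
third anticodon base when the annotation supplies the anticodon position.
The joint unit `atp8-atp6` is annotated and reported as a single gene
unit, matching the reporting convention for these overlapping genes.

## Cohort statistics

`summarize_sample()` partitions each sample's passing calls by gene class
and effect (with the invariant `synonymous + nonsynonymous + unknown =
protein-gene calls`), tabulates per-gene counts and sites-per-kb rates, and
`shared_site_counts()` builds the pairwise shared-site matrix (allele-aware
by default; position-only matching optional). `compare_groups()` compares
per-sample totals between groups with Welch's t-test by default — the
pooled-variance test is available, but group variances in this kind of data
differ by an order of magnitude, which is exactly Welch's use case — and
reports means, n−1 standard deviations and standard errors (published
summaries of such data are inconsistent about SD vs SEM, so both are
emitted). Degenerate zero-variance comparisons with equal means report
t = 0, p = 1; other zero-variance cases are an error rather than a silent
division by zero.

The package ships the per-sample and per-gene heteroplasmic-site tables of
a deep-sequencing survey of 12 human lice and 7 tick species
(`survey_tables()`), used by the worked examples and the acceptance script.
Two small internal inconsistencies present in the published per-gene vs
per-sample tables are preserved as printed and documented in the
cross-table consistency test.

## The synthetic-data generator

`sim_reference()` builds either architecture (louse preset: 20 circular
minichromosomes of 3–4 kb, 1–3 genes each; tick preset: one circular
chromosome carrying all 37 genes, ~14.3 kb of coding sequence) with
realistic gene lengths, mixed strands and a 35% GC spacer background.
`simulate_pileup()` then draws, per position, a depth (Poisson around the
configured mean — 6,000× louse, 1,700× tick — or exactly fixed), an error
count per non-reference base at rate $p/3$, and, at planted sites, a
variant count $\sim \mathrm{Bin}(n, f(1-p))$. Artifact sites can be
injected at homopolymer-adjacent positions with a 20-fold elevated error
rate — large enough (~3.3% expected frequency) that artifacts pass every
statistical filter and only the hotspot rule catches them, which is the
scenario the rule exists for. Planted non-artifact sites are placed away
from homopolymer contexts and at least 3 bp apart, so the hotspot filter
should never remove them; this is a deliberate property of the truth set,
not of real data. `emit_reads()` realises a constant-depth pileup as
FASTQ/SAM exactly (a strand-tiling construction in which each of the
`depth` read strands covers every position exactly once), so the
SAM-to-pileup path can be tested for byte-exact reconstruction; it refuses
varying-depth input rather than approximating.

What passing on this generator does **not** show about real data: the
error model is uniform and strand-symmetric (no motif-, quality- or
strand-dependent error structure beyond the injected homopolymer
artifacts), depths have no GC or amplicon-position bias, reads carry
constant qualities, and there is no alignment ambiguity because reads are
emitted pre-aligned. The generator validates the statistical machinery and
the plumbing, not the upstream mapping.

## Numerical and design choices

- All user-facing coordinates are 1-based inclusive; circular arithmetic is
  applied internally via modular index maps.
- Consensus ties go to the reference base when it is among the tied bases,
  otherwise to the alphabetically first tied base; ties between qualifying
  alternate alleles likewise break alphabetically. Determinism over
  sophistication.
- The binomial PMF is evaluated through the log-space density
  (`dbinom(log = TRUE)`), verified against an exact big-rational oracle to
  better than 1e-10 relative error up to depth 500 (and exact closed forms
  elsewhere); q-values are verified against a literal double-loop
  implementation of the step-up formula.
- Indels and reference skips never enter base counts (`find SNPs only`
  semantics); unmapped and secondary alignments are excluded.
- Zero-depth positions are carried through pileups with depth 0 and
  consensus `N` rather than dropped.
- Problem sizes in the test and acceptance runs: the full louse preset
  (~68 kb over 20 minichromosomes) for null calibration (10 seeded
  replicates at 6,000×), 1,000 planted sites at 2,000× for the power
  check, and 60 injected artifacts at 6,000× for the hotspot check —
  sizes at which every binomial/Poisson tail involved is far from its
  asymptotic regime boundaries, chosen as representative of the target
  study designs.

## Known limitations

- The caller is single-sample and biallelic-per-site by design; a
  multi-allelic site is represented by its strongest alternate and
  flagged, not split.
- $P_f$ in the default `pmf` mode is a point probability, not a tail; at
  very high depths the point mass of *any* specific $k$ becomes small, so
  the pmf screen grows more permissive with depth than a tail test would.
  Both modes are exposed; comparisons across depths should fix one mode.
- Fixed $\pi_0 = 0.05$ encodes a strong prior that most candidates passing
  the frequency screen are real; with noisier candidate sets the smoother
  estimate is preferable.
- The hotspot homopolymer rule uses the reference context only; it cannot
  see read-level homopolymer miscalls at sites whose reference flank is
  not a homopolymer.
- `emit_reads()` requires constant depth; it is a testing device, not a
  read simulator with realistic coverage profiles.
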