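---
title: "Scanning core promoter variation for natural selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning core promoter variation for natural selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprselect)
```

## The question and the design

Core promoter regions (CPRs) are the short stretches around transcription
start sites where the basal RNA polymerase II machinery assembles, guided by
elements such as the TATA box, the initiator (Inr), DPE, BREd, the DCE
subunits and MTE. In a panel of fully sequenced homozygous inbred lines with
sex-resolved expression measurements — the setting this package targets —
every line contributes one known haplotype per CPR, so three questions can be
asked jointly:

1. Does sequence variation in a CPR *explain* expression variation of the
   transcript it drives?
2. Does the CPR's site-frequency spectrum look like natural selection rather
   than neutral drift under the population's demography?
3. Can the causal nucleotides be pinned down as gains or losses of core
   promoter motif matches?

`cprselect` implements this scan end to end: per-CPR diversity statistics
with the panel's data-cleaning rules, a coalescent null for Tajima's D under
a configurable demography, expression ~ allele x sex linear models,
PSSM-based motif gain/loss calling with minimal mutation-set enumeration,
linkage screens of flanking SNPs, a read-depth duplication screen,
neighbor-joining allele phylogenies, and a synthetic cohort generator that
plants known signals so the whole pipeline can be validated without any
external download.

## Data cleaning rules

`preprocess_alignment()` applies, in order: removal of lines with
heterozygous CPR calls (inbred lines should be homozygous; residual
heterozygosity flags unreliable calls), masking of alleles rarer than 1%
(sequencing-error guard — the *allele* is masked on its carriers, the site is
kept), resolution of undetermined nucleotides (a site where determined lines
agree is treated as fixed; lines with `N` at a site that stays polymorphic
are dropped from that CPR), and exclusion of CPRs that retain fewer than 20
usable lines. The N-resolution iterates to a fixed point, which makes the
whole operation idempotent — a useful invariant when pipelines re-enter.

## Diversity and the selection test

For each cleaned CPR we report the number of segregating sites $S$,
nucleotide diversity per site

$$\pi = \binom{n}{2}^{-1} \sum_{i<j} d_{ij} / L,$$

Watterson's estimator $\theta_W = S / (a_1 L)$ with $a_1 = \sum_{i=1}^{n-1}
1/i$, and Tajima's D,

$$D = \frac{\pi L - S/a_1}{\sqrt{e_1 S + e_2 S (S-1)}},$$

with the standard constants. Sites containing `N` use pairwise deletion in
$\pi$ (each site's denominator counts only determined pairs); the sample
size entering the constants is the per-CPR count of retained lines. $D$ is
undefined for monomorphic CPRs ($S=0$) and is reported missing, never zero.

A negative $D$ (excess rare variants) is the signature of a selective sweep
or purifying selection; a positive $D$ (excess intermediate-frequency
variants) suggests balancing selection. Because demography also moves $D$,
significance is judged against a simulated null, not against the nominal
distribution.

## The coalescent null

`simulate_sample()` is a backward-in-time coalescent with recombination
(an ancestral recombination graph over the unit interval mapped to $L$
sites) supporting multiple demes with piecewise exponential growth,
instantaneous size changes, founding (split) events and discrete admixture
events. Time is measured in units of $2N_{\mathrm{ref}}$ generations;
$\theta = 4N_{\mathrm{ref}}\mu L$ and $\rho = 4N_{\mathrm{ref}} r (L-1)$,
where $r$ converts the cM/bp recombination rate at 1 cM = 0.01 crossovers.
With these conventions $\mathbb{E}[S] = \theta \sum_{i<n} 1/i$ and the mean
pairwise difference equals $\theta$, which the test suite verifies by Monte
Carlo at $n \in \{2, 10, 29\}$.

The sampled population is modelled as an admixture of an African-like deme
(with an ancestral bottleneck) and a European-like deme founded from it that
grew exponentially — the demographic scenario commonly inferred for
North-American *Drosophila melanogaster* populations. The mutation and
recombination rates default to $1.45\times10^{-9}$ events/bp/generation and
$5.0\times10^{-7}$ cM/bp. **The sizes, times and admixture proportion in
`toy_admixture_model()` are toy placeholders**: the inferred values from
demographic studies are not bundled, and analyses of real data should supply
their own `demographic_model()` or YAML file. $N_{\mathrm{ref}}$ defaults to
$10^6$, which puts $\theta$ per site at $4N\mu \approx 0.0058$ — the
magnitude observed in this species.

`build_null()` runs the simulator (100,000 replicates in a full analysis;
10,000 in the bundled end-to-end test, which keeps a one-CPU run in minutes
while leaving the 0.5% tails with ~50 observations) and collects Tajima's D
from every replicate with $S \ge 1$; monomorphic replicates, where $D$ is
undefined, are counted separately rather than imputed. `outlier_pvalue()`
uses +1-corrected empirical tails,
$p_{\mathrm{up}} = (\#\{D_{\mathrm{sim}} \ge D_{\mathrm{obs}}\}+1)/(R+1)$,
doubling the smaller tail for the two-tailed $P$; the correction avoids
$P = 0$ from finite simulation.

## Expression association

The per-transcript model is $Y = \mu + \mathrm{Seq} + \mathrm{Sex} +
\mathrm{Seq}\times\mathrm{Sex} + \varepsilon$, where `Seq` is the *full-CPR
haplotype class* (lines with identical CPR sequences share an allele label),
not a per-SNP genotype — the sequence is modelled as a unit. Per-term F
tests use Type II sums of squares, which are robust to the mild imbalance
produced by per-CPR line exclusions; with balanced data they coincide with
the other types. Benjamini–Hochberg control is applied separately per term
across transcripts (Seq, Sex, Seq:Sex form three families, matching how the
three counts are usually reported) at FDR 5%. Transcripts outside the
broad-sense heritability window 0.3–1.0 are excluded before modelling;
heritability is an input column here, not something the package estimates.

## Motif analysis

`build_pssm()` forms log-odds matrices against a uniform background with a
0.5 pseudocount per cell. The balanced threshold solves
$\mathrm{FNR}(t)/\mathrm{FPR}(t) \approx 1000$ using *exact* score
distributions computed by dynamic-programming convolution; per-cell scores
are discretized to `bin / width` (default bin 0.01 bits) so the accumulated
window-score error stays below one bin — this makes the threshold stable
under bin refinement, and the test suite checks the DP against exhaustive
enumeration of all $4^w$ words for widths 4–8. Scanning covers both strands;
windows containing `N` score missing rather than worst-case, consistent with
how undetermined data are excluded elsewhere.

A TFBS change event is a (motif, window, strand) whose binding call differs
between alleles. Following the field's classification: pattern I is one SNP
flipping one event, pattern II one SNP flipping two or more events, and
pattern III an event that only flips when two or more SNPs co-occur.
`minimal_mutation_sets()` enumerates all $2^k$ combinations of the derived
SNPs (capped at $k \le 12$, refusing beyond that) and reports the minimal
flipping subsets per event, verified in tests against direct subset
enumeration. A CPR's "number of TFBSs changed" counts *motifs* with at least
one event, not windows.

The bundled `core_promoter_motifs()` are synthetic toy matrices named after
core promoter elements. Their per-column concentrations are deliberately
graded so that some single substitutions cross the balanced threshold
(enabling pattern I) while others only cross jointly (pattern III), and the
toy MTE matrix is palindromic so one substitution can flip calls on both
strands (pattern II). Real analyses should load curated JASPAR POLII
matrices via `read_jaspar()`, which accepts both labelled-bracket and plain
4-row dialects.

## Linkage with flanking SNPs

An expression association attributed to a CPR could instead be driven by a
linked variant nearby. For each CPR, SNPs within ±5000 bp are tested
one at a time by Wald regression of line-mean expression on allele code
(lines are homozygous, so phase is known and line means are the natural
unit), with BH control at FDR 1% within the window. Haplotype blocks use the
Gabriel-style confidence-interval rule on |D′| (bootstrap percentile CIs
over lines, 1000 resamples by default): pairs are "strong LD" when the CI
lower bound ≥ 0.70 and upper bound ≥ 0.98, "recombination" when the upper
bound < 0.90, and blocks are maximal runs with no recombination pair where
strong pairs dominate informative pairs at ≥ 19:1 — since no recombination
pair is tolerated inside a block, the dominance condition reduces to
requiring strong-LD support, and blocks provably never span a pair with
direct recombination evidence. The per-CPR verdict is `Y` when some
significant flanking SNP shares a block with a CPR SNP or has $r^2 \ge 0.8$
with one, else `N`. The block-rule constants and the $r^2$ fallback are
package choices (the tool family that popularized the block definition does
not fix them in print); both are arguments.

## Duplication screen

Allele-specific duplications also change apparent expression. Reads are
prefiltered by two sequential rules: drop a read when ≥80% of its bases are
below Q20 (evaluated on the pre-trim length, since the criteria are stated
independently), then truncate the maximal 3′ suffix of bases below Q10. A
CPR is flagged in a line when mean depth over the CPR ±200 bp is at least
twice the unweighted mean of per-gene mean depths on that chromosome. The
screen is per line, since duplications of interest are allele-specific.

## Allele phylogenies

`composite_distance()` defaults to a Tamura–Nei form with base frequencies
pooled across all sequences — sharing substitution parameters across pairs
in the spirit of composite likelihood; JC and K2P closed forms are available
for degenerate data. Neighbor joining (Saitou–Nei, via `ape`) follows, with
negative branch lengths clamped to zero and the deficit moved to the sibling
branch, and rooting on a supplied outgroup (e.g. a sister-species CPR
sequence). Bootstrap support resamples alignment columns (1000 replicates by
default); figures conventionally display only supports above 60%. An allele
matching the outgroup at every segregating site is labelled ancestral.

## The synthetic cohort generator

`generate_cohort()` produces the full input bundle: coalescent CPR
haplotypes for 29 lines (160 bp by default, $\theta$ per site 0.0058),
sexed, replicated expression with a chosen broad-sense heritability
($\sigma^2_{\mathrm{line}} = h^2$, $\sigma^2_e = 1 - h^2$, additive Gaussian
noise — matching the linear model's assumptions), flanking SNPs whose
linkage to the CPR haplogroups is tuned by a per-bp label-switch probability
`ld_decay` (0 gives $r^2 = 1$, 0.5 gives independence), depth tracks, and a
truth record of every planted effect, serialized alongside the data for
automated scoring.

Planted features compose in a fixed order: TFBS variants first (writing the
motif consensus into a central window), then frequency-spectrum signals on
sites outside that window, chosen to be *motif-neutral* (a candidate site is
used only if flipping it changes no binding call), so the selection signal
and the TFBS signal stay orthogonal by construction. For balancing signals
the derived TFBS lines double as one haplogroup, so a "fully planted
positive" carries a consistent allele split across the association, the
selection test and the motif stage.

CPRs with a planted selection mode are, by default, built on a monomorphic
background (`explicit_selection_design = TRUE`) so the planted
haplotype-frequency design — and therefore its Tajima's D — is exact: a
15/14 split at 12 sites in 29 lines gives D = 3.43, decisively inside the
null's rejection region. Superimposing the same signal on a coalescent
background (set the flag to FALSE) leaves D ranging roughly 1.7–3.6 across
backgrounds, because background rare variants pull the statistic toward
zero; that mode is useful for studying the scan's power, but it makes a
planted "positive" only probabilistically positive.

Features of real data the generator deliberately does not emulate:
microarray probe-level noise and normalization artefacts, alternative
splicing, X-vs-autosome dosage, GC-dependent coverage, and sequencing-depth
noise — depth tracks are expected-coverage profiles, because the 2x
duplication rule sits exactly on the decision boundary of a noisy planted
2x signal and a probabilistic track would make the planted truth undecidable
at that threshold. The replicate count per line and sex in real panels
varies by study design and is exposed as `n_replicates` (default 2).
Passing tests therefore demonstrate the statistical machinery on clean
generative structure, not robustness to microarray artefacts.

## The pipeline's candidate definition

`run_pipeline()` runs preprocess → diversity → association → null/outliers →
motif events → linkage → duplication → phylogenies, persisting per-stage
TSVs, and reports a CPR as a candidate only when (a) its Seq term passes
FDR 5%, (b) its Tajima's D is a two-tailed outlier at $P < 0.01$, and (c) at
least one TFBS change separates alleles whose expression differs — criterion
(c) is implemented as a Welch test at 0.05 on line-mean expression between
the bound and unbound allele groups of an event. One shared null is built
per (n, L) configuration and reused across CPRs, as a single 160-bp null
suffices when CPR lengths are near their median; per-CPR nulls are a
straightforward extension. The ordering (association before the selection
screen) follows the natural data flow; both orderings give the same
candidate set since the filters are conjunctive.

## Numerical choices and limitations

* Empirical P values are +1-corrected; with $R$ replicates the smallest
  attainable two-tailed P is $2/(R+1)$.
* The balanced-threshold selection takes the achievable score whose
  FNR/FPR ratio is nearest the target on the log scale; ties resolve to the
  lower threshold.
* NJ tie-breaks are inherited from `ape`'s deterministic implementation;
  repeated runs are identical.
* The problem sizes used in the bundled tests — 10,000-replicate nulls,
  100-replicate verdict arms, 400–500-transcript association panels — were
  chosen as the package's validation scale; full analyses should raise the
  null to 100,000 replicates.
* Sweep-type signals of modest strength are hard to separate from an
  admixture-shaped null (the lower tail of D under a bottleneck/admixture
  demography is long); balancing-type outliers separate much more cleanly.
  This mirrors the asymmetry any demography-aware outlier scan faces.
* Continuous gene flow, gene conversion and ABC-based demographic inference
  are out of scope; admixture is a discrete event, and demographic
  parameters are always inputs.
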