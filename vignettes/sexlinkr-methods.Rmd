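---
title: "Discovering sex-linked markers with sexlinkr: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering sex-linked markers with sexlinkr: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sexlinkr)
```

## The problem

Most amphibians, many fish and some reptiles carry *homomorphic* sex
chromosomes: the X and Y (or Z and W) are cytologically indistinguishable, so
an individual's genetic sex cannot be read from a karyotype. Molecular
sex-linked markers fill that gap. Reduced-representation genotyping
(DArTseq, RADseq, GBS) delivers tens of thousands of SNP and
presence-absence (PA, "SilicoDArT") markers from which sex-linked loci can be
filtered by comparing genotype distributions between phenotypically sexed
males and females. Once found, such markers make sex reversal — an individual
whose gonadal phenotype contradicts its chromosomal sex — directly observable
in wild populations.

`sexlinkr` implements that analysis as a reusable, tested pipeline:

1. **Filtering** (`discover_candidates()`): sex-stratified genotype
   proportions per locus, screened by inclusive thresholds under both the
   XX-XY and ZZ-ZW hypotheses.
2. **Association** (`cochran_armitage()`): a 1-df Cochran-Armitage trend
   test of sex × genotype for each candidate.
3. **Concordance** (`hamming_matrix()`, `call_genotypic_sex()`):
   Hamming-distance agreement between individuals and majority-vote
   genotypic-sex calls from the top-ranked loci.
4. **Chance-linkage planning** (`p_spurious()`, `planning_grid()`): how many
   loci are expected to look sex-linked by chance at a given sample size.
5. **Simulation** (`simulate_dataset()`): a generative model of an XY (or
   ZW) marker system used for power, calibration and recovery testing.

`sexlink_scan()` runs stages 1–4 end to end and returns a fitted-model-style
object with `print`, `summary`, `plot` and `predict` methods.

## The filtering model

At a biallelic SNP locus the *reference allele* is the more frequently
sequenced allele; under XX-XY sex determination it is the X-borne allele, and
the *SNP allele* is Y-associated. Under tight linkage every female is
homozygous for the reference allele and every male is heterozygous. Historical
X–Y recombination ("leakage") erodes this: SNP alleles appear on X
chromosomes, producing heterozygous females and SNP-homozygous males,
increasingly so for loci far from the sex-determining region. The default
`filter_criteria()` therefore tolerates bounded departures:

| rule | default |
|---|---|
| female reference-allele homozygosity | ≥ 0.80 |
| female SNP-allele homozygosity | ≤ 0.10 |
| female heterozygosity | ≤ 0.20 |
| male reference-allele homozygosity | ≤ 0.10 |
| male heterozygosity | ≥ 0.75 |
| per-sex call rate | ≥ 0.90 |

All thresholds are inclusive ("at least"/"at most") and applied to exact
fractions, never rounded values. Genotype proportions are computed over each
sex's non-missing calls, with the call-rate rule kept separate, because an
uncalled sample is absent data rather than evidence. PA markers are scored
present/absent per sample; a locus is male-linked when its fragment is
sequenced in ≥ 90% of males and ≤ 10% of females (mirrored for
female-linked), with all samples of a sex as denominator since an
unsequenced fragment *is* the absent state for PA markers. A ZZ-ZW search is
the same rule set with the sex roles exchanged — with the defaults
(male heterozygosity ≥ 0.75, female heterozygosity ≤ 0.20) no locus can pass
both searches on the same proportions.

Cohorts (life stages, populations) are analyzed separately and compared
afterwards (`cohort_by=`), because sex-linkage can vary geographically: a
locus that recombines freely in one pond fails there while passing
everywhere else. The candidate table records per-cohort verdicts plus an
`all` / `some` / `none` cross-cohort consistency column.

## The trend test

Association is verified with the Cochran-Armitage trend test on the 2 × k
sex-by-genotype table, using dosage scores (0, 1, 2) for REF_HOM/HET/ALT_HOM
and (0, 1) for ABSENT/PRESENT — the standard choice when the trend of
interest is allele dosage. With scores $s_j$, female counts $n_{fj}$, male
counts $n_{mj}$, row totals $N_f$, $N_m$ and column totals $c_j$
($N = N_f + N_m$):

$$T = \sum_j s_j \frac{n_{fj} N_m - n_{mj} N_f}{N}, \qquad
\chi^2 = \frac{T^2}{\operatorname{Var}(T)}, \qquad
\operatorname{Var}(T) = \frac{N_f N_m}{N^2}
\left(\sum_j s_j^2 c_j - \frac{(\sum_j s_j c_j)^2}{N}\right),$$

referred to $\chi^2_1$. Under perfect separation $\chi^2 = N$; the statistic
is invariant to affine score changes; a table with all mass in one genotype
column has zero score variance and is reported as *undefined* rather than
silently zero. The test suite cross-checks the implementation against
`stats::prop.trend.test` (an algebraically identical statistic for 2 × k
tables) and against a label-permutation null; `permutation_p()` exposes that
permutation test as a small-sample companion, with the usual
$+1/(n_{perm}+1)$ correction. Raw p-values are reported (a Bonferroni column
is emitted for information only), matching how such scans are normally read.

## Concordance and genotypic-sex calling

`hamming_matrix()` computes, for each pair of individuals, the fraction of
jointly non-missing candidate loci at which their calls differ. The
pairwise-complete denominator was chosen over a fixed all-loci denominator
because the latter inflates similarity for sparsely genotyped samples; pairs
sharing fewer than `min_overlap` loci (default 1) are undefined.
`summarize_by_sex()` reports mean, standard error, minimum and maximum of
within-sex distances and flags individuals whose mean own-sex distance
exceeds `outlier_mult` (default 2) times their sex's median — a screen for
recombinant or sex-reversed individuals that replaces visual inspection of a
clustered heatmap with an explicit rule.

`rank_loci()` orders candidates by a sex-linkage score — for XY SNP loci the
mean of female reference-homozygosity and male heterozygosity, averaged over
evaluable cohorts — with ties broken by trend-test $\chi^2$ and then locus id
so the ranking is deterministic. `call_genotypic_sex()` votes across the top
`k` loci (default 3, the usual working set of best markers): under XY a call
carrying the SNP allele votes male, a reference homozygote votes female, and
the called sex is the strict majority of non-missing votes (`AMBIGUOUS` on a
tie or no data). Sex reversal is diagnosed as discordance between the called
and the phenotypic sex.

## Chance sex-linkage

With thousands of loci screened, some will mimic sex-linkage by chance. At an
autosomal locus with allele frequency 1/2, being homozygous and being
heterozygous each have probability 1/2 under Hardy-Weinberg, so the
probability that all $n$ sequenced individuals show the ideal pattern (every
female homozygous *and* every male heterozygous) is

$$P = 0.5^{\,n},$$

independent of the female:male split, and $E = L \cdot 0.5^n$ of $L$ loci are
expected to do so. `min_sample_size()` inverts this: the smallest $n$ with
$L \cdot 0.5^n$ strictly below a tolerated count (default 1). For
$L = 42{,}772$ that is $n = 16$; across locus counts typical of
reduced-representation data (≈ 4,000–43,000) the minimum ranges over roughly
12–16 individuals, which is why surveys of this kind should genotype at
least ~13 individuals of mixed sex. The model is deliberately
pattern-specific (the XY-style pattern only) and does not double for the
simultaneous ZW search; it also ignores near-miss patterns that the relaxed
thresholds admit, so it is a lower bound on false positives under loose
criteria. Powers are computed in log space and rounded only for display.

## The simulator

`simulate_dataset()` generates data under the same model the filter assumes,
plus the nuisance processes that real surveys face:

* **Sex-linked SNP loci**: an XX female draws two X alleles, each carrying
  the SNP allele with probability $q_x$ (standing recombination leakage); an
  XY male draws one X allele and one Y allele carrying the SNP allele with
  probability $y$ (`y_fidelity`). Expected class probabilities follow
  directly (see `expected_proportions()`): e.g. male SNP-homozygosity
  $q_x y$ versus female $q_x^2$ — females are rarely SNP-homozygous, the
  asymmetry the filter exploits.
* **PA markers**: present in a male if the Y carries the fragment
  (probability `y_fidelity`) or a background leak fires (`pa_leak`); present
  in a female only via the leak.
* **Sex reversal** flips the *phenotypic* label with probability `rho` while
  genotype follows the chromosomes — exactly the discordance the marker
  panel is meant to detect, so planted reversals must be recovered at rate
  `rho` by top-k calling (a standing test).
* **Population structure**: any locus parameter can be overridden per
  population, emulating ponds where particular loci lose sex-linkage.
* **Autosomal background**: unlinked Hardy-Weinberg loci with frequencies
  drawn uniformly on (0.05, 0.95), or fixed at 0.5 for calibration against
  the $0.5^n$ null.
* **Missingness** is uniform and independent per call; no sex- or
  locus-biased dropout is modeled, since surveys of this kind provide no
  dropout model to emulate.

ZW systems reuse the same code path with the heterogametic role relabeled.
A seed is mandatory and the caller's RNG state is restored, so identical
configurations are byte-identical. The default sample sizes (23 females,
54 males, one population, adults) mirror a realistic wild-adult survey; the
bundled marker tables (`racl_markers()`) carry the published green frog
(*Rana clamitans*) proportions for 12 + 13 tadpoles and 23 + 54 adults, and
the default leakage-free `locus_sim_spec()` corresponds to a perfectly
linked marker, with example configurations using $q_x \approx 0.01$–$0.15$,
$y \approx 0.85$–$0.99$ to span the proportion ranges those tables show.

What the simulator does *not* emulate — read-level error, paralog collapse,
linkage disequilibrium among markers, family structure in tadpole clutches —
bounds what passing tests prove: recovery results show the statistical
machinery is correct under its own assumptions, not that any particular
field dataset satisfies them.

## Numerical and design choices

* Replicate collapsing (`collapse_replicates()`) is conservative: replicate
  disagreement yields a missing consensus call rather than any tie-break,
  and concordance is reported over loci with at least two non-missing
  replicates.
* The two-row genotype dialect decodes the score pair (0,0) — and blanks —
  as missing, not as a null genotype.
* Un-evaluable cohorts (lacking either sex) produce explicit `NA`/
  `NOT_EVALUABLE` verdicts, distinct from failures.
* `sexlink_scan(system = "auto")` evaluates both hypotheses and adopts the
  one yielding more candidates, XY on a tie; the choice is recorded in the
  fitted object.
* Degenerate trend tables are flagged, never coerced to $\chi^2 = 0$.
* Fixture tests rebuild count-level inputs whose exact fractions round to
  the published two-decimal proportions, so threshold comparisons never
  depend on rounded values.

Two known discrepancies in the bundled tables are treated as data, not
forced to fit: the RaclCT004 adult row (male reference-homozygosity 0.13)
breaches the strict 0.10 rule despite the locus's discovery in both cohorts,
and the RaclCT021 adult row satisfies the strict PA thresholds despite its
tadpole-only discovery annotation. The regression tests assert today's
criteria-faithful behaviour and document both exceptions.

## Problem sizes used in the test suite

The suite favours many small, seeded simulations over few large ones: null
calibration uses 2,000 trend tables of 100 individuals; the Monte-Carlo
check of $L \cdot 0.5^n$ uses 200 replicates of 5,000 loci × 10 individuals;
parameter and sex-reversal recovery use 500 individuals per sex; end-to-end
scans use 23 + 54 individuals with up to ~2,000 background loci. These sizes
put every stochastic assertion within three standard errors of its target
under the fixed seeds while keeping the whole suite fast.

## Limitations

* The chance-linkage model covers only the exact ideal pattern; expected
  false-positive counts under the relaxed thresholds are higher.
* Trend tests assume independent individuals; tadpoles from shared clutches
  violate this, which is why the conservative one-pair-per-clutch sample
  size matters in planning.
* Genotypic-sex calls from `k` loci inherit those loci's linkage: a cluster
  of co-inherited recombinant markers can make one individual look
  discordant at several loci at once without sex reversal. The top-k rule
  with small `k` of the *best* loci mitigates but does not remove this.
* The package does not construct linkage maps, phase haplotypes, or call
  markers from reads; it begins at the genotype matrix.
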