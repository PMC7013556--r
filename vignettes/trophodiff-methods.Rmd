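---
title: "Methods: time-course analysis of villous trophoblast differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-course analysis of villous trophoblast differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophodiff)
```

## The biological setting and the pipeline

Villous cytotrophoblasts are the proliferative progenitors of the human
placental barrier. In culture they differentiate over about a week,
fusing into the multinucleated syncytiotrophoblast that carries most
placental functions. `trophodiff` implements a complete analysis pipeline
for log2-scale expression time courses of this process — days 0..7 with
replicate arrays per day — and for overlaying an external disease
differential-expression table (preterm preeclampsia style) on the result.

The stages, in order: per-day differential expression against two
baselines; Fisher-exact enrichment machinery (chromosomes, co-expression
modules, arbitrary GMT gene-set collections); weighted co-expression
module detection; selection of a high-expression-change (HEC) threshold
from a PPE-enrichment curve and temporal clustering of the HEC genes;
transcription-regulator (TR) network inference from co-expression and
from DNaseI footprint/motif/TSS intervals; topology-propagated pathway
impact analysis; and the disease overlay with a permutation test of
discordant-gene co-expression tightness. `run_pipeline()` chains all
stages; every stage is also exported on its own.

## Differential expression

Fold changes are differences of day-mean log2 intensities — for day $d$,
versus day 0 and versus day $d-1$. Significance per comparison uses an
empirical-Bayes moderated $t$: with per-gene pooled variance $s_g^2$ on
$f$ degrees of freedom, the posterior variance is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + f\, s_g^2}{d_0 + f},\qquad
\tilde t_g = \frac{\Delta_g}{\tilde s_g\sqrt{1/n_a + 1/n_b}},$$

referred to a $t$ distribution with $d_0 + f$ degrees of freedom. The
hyperparameters $(d_0, s_0^2)$ come from method of moments on
$\log s_g^2$, using the log-F moments
$E[\log s^2] = \log s_0^2 + \psi(f/2) - \log(f/2) - \psi(d_0/2) + \log(d_0/2)$
and $\mathrm{Var}[\log s^2] = \psi'(f/2) + \psi'(d_0/2)$, with a Newton
solve of the trigamma inverse. Two guards matter in practice:

* if the observed spread of $\log s^2$ does not exceed its expected
  sampling spread, $d_0$ is set to infinity (full shrinkage, normal
  reference distribution);
* genes with zero posterior variance and a non-zero mean difference get
  $p = 0$ (the noise-free limit used by the recovery tests), and designs
  with fewer than two replicates per group degrade to fold-change-only
  calling with an explicit warning.

Forcing `d0 = 0` reproduces the ordinary pooled two-sample $t$ exactly,
and `d0 = Inf` the $z$ statistic against $s_0$; both limits are asserted
at `1e-12` in the test suite, and the default fit is cross-checked
against an independent empirical-Bayes implementation (limma) on a
heteroskedastic fixture.

A gene is differentially expressed (DE) when on **some single day**
$|\log_2 \mathrm{FC}|$ vs day 0 is at least $\log_2 2$ **and** the
BH-adjusted $p$ of that same day's comparison is below 0.1. A
fold-change-and-FDR rule could in principle let the two conditions fall
on different days; this package deliberately requires them to coincide,
because a significance value belongs to exactly one comparison. BH
adjustment is applied within each day's comparison family (one family
per analysis, matching per-analysis reporting conventions).

Constitutively high expression flags genes whose minimum day-mean
intensity stays at least 4-fold above a supplied background level; day
means are taken on the log2 scale (geometric means), consistent with the
fold-change definitions, and the boundary is inclusive.

## Enrichment statistics

All enrichment uses 2×2 Fisher machinery. Effect sizes are raw
cross-product odds ratios $\mathrm{OR} = ad/bc$ — this is the form that
reproduces printed module-table values — with a Haldane–Anscombe +0.5
correction **for display only** when a cell is zero, never entering the
p-value. Exact p-values are two-sided by the point-probability rule by
default (one-sided exposed; gene-set over-representation uses the
one-sided upper tail, equivalently the hypergeometric tail). The test
suite checks the p-value against a brute-force enumeration oracle over
all tables with $N \le 30$. GMT collections are intersected with the
universe before testing; per-collection BH families; the significance
default for gene-set calls is $q < 0.2$. Coverage (the percentage of a
query set inside a term) is reported alongside.

## Co-expression modules

Profiles are the eight day means per gene. Adjacency is unsigned,
$a_{ij} = |\mathrm{cor}_{ij}|^\beta$ — the classic default, and
consistent with the absolute-correlation convention the network stages
use throughout. $\beta$ is chosen as the smallest power
whose degree distribution fits scale-free topology with $R^2 \ge 0.8$
(log-binned regression over at least 5 occupied bins; fallback 9 with a
warning). Similarity is the topological overlap measure

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}},$$

and modules come from average-linkage clustering of $1-\mathrm{TOM}$
with a **static cut** at the 0.99 quantile of merge heights — simpler
and fully deterministic compared to the dynamic hybrid cut, and
sufficient for the recovery benchmarks; the quantile is exposed. Two
numerical details: average-linkage merge heights are clamped monotone
(floating-point ties can produce epsilon inversions), and the cut height
gets a `1e-8` tolerance so merges exactly at the cut stay merged —
without it, exact tie blocks in noise-free data split arbitrarily.
Clusters below 30 genes are unassigned; labels M1..Mk are ordered by
decreasing size, with conventional module colors.

A module is classified "placental" when one-sided PPE enrichment has
$\mathrm{OR} > 1$ and $p < 0.05$; module and group trajectories are mean
$|\log_2\mathrm{FC}|$ curves, the group curve being the gene-weighted
mean of its modules. With only 8 observations behind each correlation,
module claims rest on recovery benchmarks, not on correlation inference.

## HEC threshold and temporal clusters

The HEC threshold is read off the curve of PPE-enrichment odds ratios as
a function of the log2 fold-change threshold (grid 0.1..4.0, step 0.1).
An analyst reads such a curve by eye, choosing the point where its slope
turns sharply upward; the computable rule here returns the smallest grid
point whose forward difference exceeds `slope_factor = 3` times the
median positive forward difference. A manual override — default 2.5,
about 5.7-fold, the canonical choice for this assay — wins when
supplied, with the automatic choice logged, so the reproducible rule and
the analyst's judgement can be compared on every run. The enrichment
universe defaults to all measured genes (so the HEC set is a top
fraction of the whole array, not of the DE set); restriction to DE genes
is a caller choice via the `universe` argument.

HEC trajectories (log2FC vs day 0, with the day-0 zero included) are
clustered hierarchically with correlation distance $1-r$ and average
linkage, cut to $k = 5$ clusters. Correlation distance and average
linkage are chosen because cluster identity is about trajectory *shape*,
not amplitude (assignments are invariant to positive scaling); both are
free parameters. Clusters are renumbered C1..Ck by
time-to-half-maximum of the mean |trajectory|, so C1 is the
immediate-response cluster. Fewer distinct profiles than $k$ reduce $k$
with a warning.

## Regulator networks, footprints, and the disease overlay

The TR co-expression network connects every DE TR gene to every DE gene
with $|r| \ge 0.9$ over the eight day means (TR–TR pairs once);
connectivity is the neighbor count. The footprint network creates an
edge TF→gene when a motif instance named for the TF overlaps a DNaseI
footprint by at least 1 bp and lies entirely within the gene's
promoter window, default −5000..+1000 around the TSS, strand-aware,
0-based half-open on the BED side (the exact window is unstated in the
footprint-mapping literature this follows; it is a config value).
Interval arithmetic goes through GenomicRanges/IRanges and BED files
through rtracklayer. Edges are then filtered by expression correlation
with a **strict** $|r| > 0.6$ rule; TFs without a mappable gene id are
counted and reported, not silently dropped. Per-TF coverage of
placental/non-placental module-group genes is reported with the 4%/5%/10%
flags used to rank regulators.

The disease overlay classifies TR genes DE in both contexts by fold-change
sign — the differentiation fold change is the signed log2FC at the day of
maximum |log2FC| — into concordant and discordant sets. The tightness of
the discordant set is its mean pairwise |r|, with a permutation null of
equal-size random subsets of the DE TR pool,
$p = (\#\{\mathrm{null} \ge \mathrm{obs}\} + 1)/(B + 1)$. Mean pairwise
|r| is used because "tight clustering" in a co-expression layout is
proximity in correlation space.

## Pathway impact analysis

Signed directed pathway graphs (±1 activation/inhibition; compound edge
types are expected to be collapsed to signs upstream) define the
influence matrix $B_{gu} = \beta_{ug}/N_{ds}(u)$, normalizing each
regulator by its number of downstream edges. Perturbation factors solve
$PF = \Delta E + B\,PF$; the accumulation $\mathrm{Acc} = PF - \Delta E$
sums to the pathway statistic $tA$. Singular systems (e.g. unit-gain
feedback loops) mark the pathway non-evaluable rather than failing the
run. $p_{ORA}$ is the hypergeometric upper tail of the DE count;
$p_{Acc}$ is a bootstrap: $B$ rounds place the observed DE fold changes
on uniformly chosen pathway genes and recompute $tA$ (via its linearity
in $\Delta E$ — $tA = w^\top \Delta E$ with
$w = \mathbf{1}^\top(I-B)^{-1} - \mathbf{1}^\top$), the null is
median-centred (standard impact-analysis practice), and the p-value uses
the +1 count correction. The combination is the product closed form
$p_G = c - c\ln c$, $c = p_{ORA}\,p_{Acc}$, which is exact for
independent uniform p-values and is the documented choice here.

## The synthetic-data generator

`generate_timecourse()` emulates the study design: 8 days × 3
replicates, log2 intensities `baseline + amplitude · sign · f(day) +
N(0, rep_sigma)`, with uniform baselines in 6..12 log2 units so the
constitutive rule is exercisable against a configurable background.
Temporal archetypes are: flat, immediate-transient (day-1 peak),
immediate-persistent (day-1 step), slow-persistent (ramp to day 5), and
additionally mid-transient (day-3 peak) and late-transient (day-5 peak).
The two extra shapes exist because unsigned adjacency makes up- and
down-variants of one shape indistinguishable ($|r| = 1$), so a
five-module recovery benchmark needs five *shape*-distinct archetypes;
the maximum pairwise template correlation of the five non-flat shapes is
0.64 (derived analytically). Amplitudes are log-normal (median 2 log2
units, sdlog 0.4); PPE genes draw amplitudes with twice the mean, which
is what makes PPE-vs-background fold-change comparisons and the
HEC-curve benchmarks reproducible. PPE labels are enriched in the
slowly-changing modules (fraction 0.25 vs 0.02) and on one designated
chromosome (default chr19-like, 4× oversampling). Defaults plant five
modules at 6/8/5/7/4% of the gene count, the rest flat background.

What the generator does **not** emulate: probe-level microarray
artifacts, normalization, batch effects, correlated replicate noise, or
realistic between-gene correlation inside the flat background. Passing
recovery tests therefore show the estimators invert this generative
model at realistic noise levels — not that real arrays meet the model's
assumptions.

Companion fixtures give every downstream stage a recoverable answer:
`generate_disease_table()` flips the fold-change sign of a chosen DE TR
subset (the overlay must return exactly that set);
`generate_footprint_fixtures()` plants TF→gene motif/footprint/TSS
triples on a toy chromosome plus decoys that must produce no edges;
`generate_pathway_fixture()` emits random signed DAGs (or graphs with a
guaranteed 2-cycle). `simulate_fc_breakpoint()` builds a gene population
whose PPE odds-ratio curve rises linearly (0.3 per grid step) below a
planted breakpoint and jumps (≈2.0 per step) just above it; the non-PPE
fold-change tail decays exponentially above the breakpoint because a
uniform tail makes an odds-ratio jump mathematically impossible with a
monotone PPE survival curve. At 20 000 genes / 3 000 PPE the forward-
difference noise (SD ≈ 0.13) sits far from both failure modes of the
slope rule.

## Problem sizes and determinism

The shipped benchmarks use 2 000-gene expression sets (module recovery
over 20 seeds at replicate noise 0.3), 20 000-gene fold-change
populations for threshold selection, and 2 000 random 50-node pathways
(bootstrap B = 1000) for null calibration of $p_G$ — sizes chosen so the
full suite and the acceptance script each run in minutes on a single
core while keeping every Monte-Carlo margin several standard errors wide.
Every stochastic step takes an explicit seed; `run_pipeline()` derives
per-stage seeds from one master seed, and reruns are byte-identical.

## Known limitations

* Correlations over 8 day-means carry ~6 degrees of freedom; network
  edges at $|r| \ge 0.9$ are descriptive, not significance-calibrated.
* The static quantile tree cut has no merging of close modules; module
  counts at intermediate noise can differ from the dynamic hybrid cut.
* $p_{Acc}$ resamples fold changes independently of the pathway's gene
  identities; correlated DE structure on a pathway is not modelled.
* The footprint mapper trusts its motif instances; no sequence-level
  motif scanning is performed.
* With a single replicate per day the pipeline degrades to fold-change-
  only DE calling (warned), as no within-day variance is estimable.
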