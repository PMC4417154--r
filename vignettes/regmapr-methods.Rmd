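---
title: "Models and methods behind regmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind regmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(regmapr)
```

`regmapr` builds a regulatory map for a multicellular system from three
inputs: TF binding motifs, per-stage chromatin accessibility, and a gene
expression atlas. This vignette explains each model in the pipeline, the
parameters that matter, the synthetic world used for validation, and the
numerical and design decisions that were genuinely open.

## 1. Window motif scoring

### The model

The genome is tiled into windows of `window_length` bp (default 500)
every `stride` bp (default 50); windows that would extend past the
chromosome end are not created. Each window is scored against a PWM
with a generative sequence model: scanning left to right, position $i$
is emitted either as a background base, with probability
$(1-p)\,\mathrm{bg}(x_i \mid \text{context})$, or — if at least $w$
bases have been consumed — as the final base of a motif site, with
probability $p \cdot \tfrac12\!\left(P_W(x_{i-w+1..i}) +
P_W(\mathrm{revcomp})\right)$. The likelihood follows the forward
recursion

$$F(i) = (1-p)\,\mathrm{bg}(x_i)\,F(i-1) + [i \ge w]\; p\,e(i)\,F(i-w),
\qquad L(p) = F(n).$$

The free parameter $p$ — the per-position site-entry probability, i.e.
the site density — is fitted per window by EM: the E-step computes the
posterior expected number of sites $n_s$ by forward–backward, and since
every position is either inside a site or a background emission,
$n_b = n - w\,n_s$ and the M-step is $p \leftarrow n_s/(n_s + n_b)$.
The reported score is $\log L(\hat p) - \log L(0)$ in nats, clamped at
0 (since $p = 0$ is always feasible). It integrates any number of
strong or weak sites on either strand.

Internally the recursion is computed in *background-ratio form*:
dividing $F$ through by the running background product gives
$G(i) = (1-p)G(i-1) + p\,r(i)\,G(i-w)$ with
$r(i) = e(i)/\prod \mathrm{bg}$, so that $\log G(n)$ *is* the score.
This is algebraically identical to the plain recursion (the test suite
verifies it against a brute-force enumeration of all non-overlapping
site placements to $10^{-9}$ relative error) and numerically stabler;
the rare window that still over- or underflows is redone with
power-of-$10^{250}$ rescaling.

### Parameters

* `p_init = 1/(4w)` — EM start; any interior point works, this one is a
  site every four motif lengths.
* `p_max = 1/w` — cap on the fitted density. One site per motif length
  is the physical packing limit; the cap prevents degenerate all-site
  solutions on repetitive sequence. The cap is applied inside the
  M-step, which keeps the EM ascent property (constrained M-step).
* convergence — $|\Delta \log L| < 10^{-9}$ or 200 iterations; a fitted
  $p$ below $10^{-8}$ is snapped to the $p = 0$ boundary.
* background — order-1 Markov chain trained once per genome
  (configurable order). Contexts never observed fall back to the
  marginal. Non-ACGT bases emit as background with probability 0.25 and
  can never lie inside a site; windows shorter than the motif score 0.

### Multi-species averaging

Motif scores of orthologous segments from related species are combined
as a weighted average, with weights renormalised over the species that
actually have a segment for the window — a missing alignment is treated
as missing data, not as evidence of absent binding. Weights are
supplied with the orthology map; the synthetic world derives them from
a fixed toy tree as $w_i \propto e^{-d_i}$. Per-species backgrounds are
trained on each species' own sequence.

## 2. Accessibility masking

Per-stage accessibility arrives as a base-level bedGraph, is averaged
into windows (mean over the `stride`-bp subsegments of the maximum
per-base value in each; uncovered bases count 0), and thresholded:
exactly $\lfloor 0.10\,N \rfloor$ windows are marked accessible, chosen
by descending value with ties at the cut broken by genomic order.
Masked-out windows carry score 0 (not missing), so downstream max/mean
aggregations stay defined.

## 3. TF–domain associations

For a TF with motif $m$ and a domain $D$ with developmental stage
$s(D)$:

1. mask the multi-species motif track with stage $s(D)$'s
   accessibility mask;
2. score each gene as the **maximum** masked window score over its
   regulatory region (max rather than sum/mean — both selectable —
   because the window score already integrates sites);
3. rank genes **within the universe** (atlas genes with a non-empty
   region under the mode) and keep the top
   $k = \min(1000, 0.2\,|\text{universe}|)$ with positive scores (ties
   by gene id; genes with score 0 are excluded even if $k$ is unmet);
4. test the overlap $x$ of this target set (size $n$) with the domain's
   gene set (size $K$) by the hypergeometric upper tail
   $P(X \ge x)$ in a universe of $N$;
5. repeat for the three regulatory-region definitions — `p1K` (1 kb
   upstream of the TSS, strand-aware), `p5K` (5 kb upstream), `IG`
   (gene span extended up to 50 kb per side, truncated at the nearest
   insulator mark) — and keep the smallest p-value (ties resolved
   p1K > p5K > IG). $S = -\log_{10} p$, capped at 300 so downstream
   features stay finite when $p$ underflows.

Expression support of an association is classified as `specific` (TF
gene annotated with the domain), `related` (annotated with an ontology
ancestor or descendant of the same stage), `ubiquitous` (TF flagged
ubiquitously expressed in the stage), or `none`. Proximal/distal bias:
an association significant under one region class
($p < \alpha_{sig} = 10^{-7}$) and clearly not under the other
($p > \alpha_{null} = 10^{-3}$) is class-specific; per TF and per
domain the split of specific counts is tested against 0.5 with an
exact two-sided binomial test.

A caution validated during testing: the intuitive monotonicity "adding
a gene to both target set and domain set can only strengthen the
association" is provably false near the support boundary of the
hypergeometric (when $n + K$ approaches $N$ the minimum possible
overlap rises and the tail can jump to 1); it holds, and is tested
exhaustively, in the sparse regime ($K, n \le N/4$) where the method
operates.

## 4. Enhancer activity models

**Open regions.** Windows accessible in any stage are reduced to a
non-overlapping set greedily by descending maximum-stage accessibility.
Regions whose motif content — the maximum unmasked multi-species window
score over all motifs, over the windows overlapping the interval — is
below the 5th percentile of the same statistic over the labelled
reference enhancers are dropped. The statistic is computed identically
for regions and reference enhancers; an asymmetric variant (region =
own window only) biases the threshold upward and starves the training
sets.

**Candidate domains.** Each region is annotated with its two nearest
genes (distance to the gene span, 0 if overlapping, ties by gene id)
and the union of their atlas domains; regions with no annotated
neighbour are discarded.

**Training sets.** For domain $D$: positives are regions with a
neighbour annotated with $D$ within 5 kb, accessible in $s(D)$, not
overlapping any reference enhancer, capped at 500 by a seeded
subsample; negatives are an equal-sized seeded sample of
stage-accessible regions with no neighbour annotated with $D$ and no
reference overlap; the split is a stratified, seeded 75/25. Domains
with fewer than 10 of either class are skipped with a recorded reason.
These labels are intentionally *noisy* — proximity and annotation stand
in for unavailable validated enhancers — which also leaves the labelled
reference set untouched as test data.

**The model.** For each domain a ridge-regularised least-squares fit on
raw features against the 0/1 labels:

$$y^r = \sum_m \alpha_m\, Z^r_m\, S^D_m\, E^D_m\, R^D_m
      + \sum_s \gamma_s A^r_s + \beta$$

with $Z$ the region's unmasked multi-species motif score (accessibility
enters separately through $A$), $S$ the association strength, $E$ the
0/1 expression indicator (`specific`/`related`/`ubiquitous` count as
expressed), $R$ the TF's FPKM in the domain's stage, and $A_s$ the
region's per-stage accessibility. The default penalty
$\lambda = 10^{-6}$ keeps the solve well-posed without materially
shrinking coefficients; the intercept is unpenalised. A linear
least-squares classifier is used deliberately — simple, deterministic,
and adequate for a ranking task.

**Gating and annotation.** A model is *good* if its reference-based
RFVO AUROC exceeds 0.7 (computed only when at least 10
reference-overlapping regions carry the domain) or its left-out test
AUROC exceeds 0.6. Gated models score all open regions; a domain is
assigned to a region when a neighbour gene carries the domain and the
region's score reaches the inclusive 95th empirical percentile. For
regions overlapping a labelled reference enhancer, candidate domains
with gated models are ranked by score percentile and the rank statistic
is $1$ for $k = 1$, else $(k - \text{rank}_{true})/(k - 1)$ (best true
domain if several; average ranks on ties).

## 5. The synthetic world

`simulate_world()` plants a fully known regulatory system:

* 2 chromosomes × 300 kb of i.i.d. sequence at GC 0.40;
* 20 TFs with 6–10 bp PWMs, one dominant base per column with
  probability drawn in 0.85–0.99 — high-information columns, as in the
  in vitro collections being emulated, and necessary for detectability:
  a site only registers in the window score once its log-odds clearly
  exceed $\log(500) \approx 6.2$ nats;
* a TF → domain map planted at density 0.15 over 12 domains (four
  stages, round-robin), every domain guaranteed one regulator;
* 120 genes on a regular spacing with jitter; 8 enhancers per domain of
  500 bp, placed strand-aware within the 5 kb upstream neighbourhood of
  their target TSS, each carrying 4 sites cycling through the domain's
  regulators (every regulator is represented — the cooperative-binding
  structure the planted map asserts);
* per-stage accessibility = Gaussian bumps (height 8, sd 300 bp) over
  the stage's enhancers plus |N(0,1)| background noise, written as
  50 bp-bin bedGraph; ChIP-like tracks per TF likewise (kernel sd
  200 bp, height 5, noise 0.5);
* 3 ortholog genomes mutated at 0.15/bp with planted sites preserved
  intact with probability 0.8 per site per species, 5% of window
  segments missing; species weights from a fixed toy tree;
* insulator marks (80 × 200 bp) sampled so that they never separate a
  planted enhancer from its target gene — insulators delimit regulatory
  domains, and a planted enhancer–gene pair lies within one by
  construction;
* atlas annotations driven by the planted enhancers plus a 2% rate of
  random extra annotations (a minority, so domain gene sets are
  genuinely "driven by" the planted map); TF FPKM lognormal, ×8 in
  stages where the TF is active; 30% of enhancers exported as the
  labelled reference set.

Everything is deterministic given the single seed.

### What the synthetic world does and does not show

It preserves the statistical structure the pipeline relies on — planted
sites inside accessible enhancers, stage-specific masks, domain gene
sets driven by a planted map, partial cross-species conservation, noisy
ChIP-like occupancy — at a scale (hundreds of kb, tens of TFs) where
the full pipeline runs in about a minute. It does **not** imitate real
genome composition, repeat structure, motif families with shared
specificities, a real phylogeny, or atlas vocabulary; passing recovery
tests here demonstrates internal correctness and end-to-end signal
propagation, not expected accuracy on real data.

Two desk-scale limits are worth stating plainly, because the recovery
experiments run up against them. First, short motifs (6–7 bp) are
near-invisible to a 500 bp window score even at high information
content — a perfect 6-mer carries ~7–8 nats of log-odds against a
~6.2-nat site-density penalty — so TF–domain pairs whose regulator has
a short motif are recovered weakly, and the mean association AUROC over
default worlds sits around 0.85–0.89 rather than higher. Second, with
~30 labelled reference enhancers and 12 domains, over half of the
reference-overlapping open regions have a single candidate domain, for
which the rank statistic is trivially 1 under any labelling; this caps
how far the real ranking can beat a label-shuffled control. Both are
properties of the study scale, not of the algorithms; the oracle
equivalence tests (likelihood enumeration, hypergeometric enumeration,
pairwise AUROC) pin down the algorithms themselves exactly.

### Problem sizes used in the tests

Unit tests use a 1 × 150 kb world (8 TFs, 30 genes, 6 domains); the
chance-level control uses a 1 × 240 kb world with no planted sites; the
recovery experiments use the full default world with 5 seeds. The
complete suite runs in roughly 15 minutes on one CPU.

## 6. Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere (BED convention).
* `top_fraction_mask` selects exactly $\lfloor fN \rfloor$ windows,
  deterministic under ties; missing values are never selected.
* Hypergeometric tails come from `stats::phyper`; exact binomial bias
  tests from `stats::binom.test`; correlation p-values from the
  two-sided t-transform $t = r\sqrt{(n-2)/(1-r^2)}$ (for Spearman the
  usual large-n approximation), with $|r| = 1$ reported as $p = 0$.
* AUROC uses midrank ties (Mann–Whitney); the curve sweeps descending
  thresholds with tied scores moving together.
* Empty regulatory regions (clipped at chromosome bounds) are legal and
  simply contribute no windows; genes with no overlapping windows score
  0; an empty target set yields $p = 1$.
* All sampling (eval-window draws, training subsets, splits, the
  generator) is governed by explicit seeds and leaves the caller's RNG
  state untouched.

## 7. Known limitations

* The background model is global per genome; a window-local background
  is not offered.
* Phylogenetic weights are taken as input, not estimated from a tree.
* Motif-similarity clustering between TFs is not performed; highly
  similar motifs will produce correlated associations.
* The linear activity model is a ranking device; its coefficients are
  not effect-size estimates and collinearity among co-regulators makes
  individual $\alpha_m$ uninterpretable.
* RFVO evaluation requires at least 10 reference-overlapping regions
  per domain and is therefore silent on reference-poor worlds.
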