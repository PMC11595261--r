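---
title: "Eliminative RadViz cascades: model, design choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eliminative RadViz cascades: model, design choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvcascade)
```

## The model

`rvcascade` predicts a binary therapy response (resistant vs sensitive, in
the FOLFOX colorectal-cancer setting that motivated the package) by an
*eliminative cascade* over radial projections of small gene panels. The
method trades a single decision boundary for an ordered list of simple,
visually interpretable rules, and trades forced calls for an explicit
`undetermined` category.

### Radial projection

A layout places $k \in \{3,4\}$ genes as anchors on the unit circle,
$A_i = (\cos\theta_i, \sin\theta_i)$. Expression values are min–max
normalized per gene to weights $u_i \in [0,1]$ using bounds learned from a
reference cohort, and a sample is placed at

$$p = \frac{\sum_i u_i A_i}{\sum_i u_i},$$

which is the unique zero of the spring-force sum $\sum_i u_i (A_i - p)$:
each gene pulls the sample toward its anchor with stiffness proportional to
its normalized value, and the sample settles where the forces balance. The
package also ships `spring_oracle()`, a numeric minimizer of the spring
energy $\tfrac12\sum_i u_i \lVert A_i - p\rVert^2$, used *only* as an
independent cross-check of the closed form in the tests — never as the
implementation.

Two consequences the tests rely on: every point is a convex combination of
anchors (so it lies in their convex hull), and scaling a sample's weight
vector by any positive constant leaves its position unchanged (only the
*profile* across the panel matters, not overall intensity).

### Elimination regions

A region is the closed angular sector between two anchors adjacent in the
layout — the "quarter" of a four-anchor layout or the "arm" of a
three-anchor one — intersected with radius $\ge r_\min$. The closed-arc
convention means a point exactly on an anchor ray belongs to both adjacent
sectors; ties between the two labeled regions of a final step are resolved
in favour of the region listed first. The dead zone around the origin
(default $r_\min = 0.05$) exists because the origin is the maximally
ambiguous point: a sample with a flat profile projects there regardless of
class, and an all-zero weight vector is defined to project there and is
therefore never called.

### Differential expression and marker selection

Group comparisons use a moderated t-statistic: per-gene pooled two-sample
variances $s^2$ on $d = n_1 + n_2 - 2$ df are shrunk toward an
empirical-Bayes prior, $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, with
$(d_0, s_0^2)$ estimated by moment matching of $\log s^2$ across genes
(inverting the trigamma function for $d_0$; when the observed spread of
$\log s^2$ does not exceed its sampling noise, $d_0 = \infty$ and all genes
share $s_0^2$, estimated by the mean of $s^2$). The statistic is referred
to a t distribution on $d_0 + d$ df (normal when $d_0 = \infty$).
`limma::eBayes` implements the same estimator and serves as the
cross-check oracle in the test suite. Benjamini–Hochberg adjustment is
delegated to `stats::p.adjust`.

Primary markers in one cohort satisfy raw $p < 0.05$ and $|t| > 2$, both
strict. The two-stage panel rule across three cohorts:

1. a gene is a candidate if it passes the primary filter in the same
   direction in at least two cohorts;
2. it is excluded if, in the remaining cohort, the mean difference has the
   opposite sign, $|t| < 1$, or $p \ge 0.075$ — i.e. survivors must show at
   least "acceptable" same-direction evidence where they missed the primary
   cut;
3. genes significant in all three cohorts (the triple-intersection core)
   are always kept.

The secondary thresholds are retention criteria: reading them as bare
exclusions would contradict the requirement that survivors show acceptable
significance in the remaining cohort, so the package retains a gene only
when all three secondary conditions hold there.

### Cascade training

Interactive visual analysis picks projections by eye and draws elimination
boundaries by hand. A reproducible artifact needs an objective criterion,
so `fit_step()` replaces both with an exhaustive, deterministic search: all
gene subsets of size $k$ from a candidate pool, all distinct circular
orderings (rotations and reflections collapsed, $(k-1)!/2$ per subset), and
all $k$ adjacent-anchor sectors. A candidate qualifies when its *purity*
(fraction of covered samples carrying the step's target label) and
*coverage* (count covered) clear their floors on a random 70% stratified
training split **and** on the full cohort; among qualifiers the maximal
full-cohort coverage wins, ties broken by purity and then lexicographic
gene order, which makes refits bit-identical under a fixed seed.

Defaults follow the eliminative philosophy: `purity_min = 1` (steps remove
homogeneous samples only), `coverage_min = 3` (a rule must explain at least
a handful of samples to be worth a step), `train_frac = 0.7`. The final
step of a schedule fits one region per label on a shared layout with a
relaxed floor (`final_purity_min = 0.8`), because by then only the hard,
boundary samples remain and a homogeneity requirement would simply refuse
to call anything; when no shared layout yields qualifying sectors for both
classes (typical when one class is nearly exhausted), it falls back to the
best single labeled region and leaves the rest mixed.

Two design choices depart from the plain search and deserve justification:

- **Margin qualification** (`margin`, default 10° in `fit_cascade()`, off
  in the base `fit_step()`): a qualifying sector must keep its purity when
  inflated by the margin on both ends. Bare coverage maximization selects
  arcs flush against opposite-class training samples, which generalize
  measurably worse to held-out cohorts; the margin is the search-space
  analogue of not drawing a boundary through the middle of a cluster.
- **Pool ranking**: the exhaustive search is combinatorially capped at
  `max_pool = 12` genes per step. `fit_step()` refuses larger pools and
  asks for a pre-ranked subset; `fit_cascade()` automates exactly that,
  ranking the unused panel genes by $|t|$ on the samples still in play
  (stratified by panel direction) so later steps draw the genes most
  informative for the leftover subpopulation.

### Normalization: frozen vs per-step

Interactive tools rescale the display to the samples currently shown, which
would make each step's geometry depend on which samples remain — and
predictions on a new cohort depend on the cohort's composition. The package
therefore **freezes** min–max bounds at training time: each step stores the
bounds fitted on the samples in play when it was trained, and prediction
clips out-of-range values into $[0,1]$. This makes predictions
deterministic, sample-order independent (applying a cascade to a
concatenation of two cohorts equals concatenating the per-cohort results),
and single-sample capable. The alternative reading is preserved behind
`apply_cascade(..., renormalize = TRUE)`. Constant genes normalize to a
neutral weight of 0.5.

## The synthetic generator

`generate_cohort()` emulates the statistical structure the method assumes,
not any particular microarray platform:

- a marker panel of "up" genes elevated and "down" genes reduced in
  resistant samples, by `effect_size` (default 1.5) per-gene SDs; the
  default panel has 20 up and 10 down genes, mirroring the published
  FOLFOX marker panel's composition;
- positive within-panel correlation (`rho_within`, default 0.3) and
  negative cross-panel correlation (`rho_cross`, default −0.2) via a
  two-factor Gaussian block model (a shared factor with opposite loadings
  on the two panels plus one factor per panel), which is positive
  semi-definite by construction and requires
  $|\rho_\text{cross}| \le \rho_\text{within}$;
- resistant-subtype heterogeneity: with `subtypes = s`, the up panel is
  partitioned into $s$ disjoint subsets and each resistant sample elevates
  only its subtype's subset, so no single sector step can cover every
  resistant sample — the property that makes the cascade multi-step;
- independent background genes, and an arbitrary log-like scale centred at
  8 with SD 1, echoing microarray log2 intensities (all downstream code is
  scale-agnostic).

The correlation defaults were fixed once as a realistic middle ground; note
that the shared factor is a genuine confound — a sensitive sample with a
+2 SD factor draw gains ~0.9 SD on every up gene and loses it on every down
gene, i.e. the generator deliberately produces class impostors that no
classifier on these genes can call correctly.

What the generator does **not** emulate: probe-level artifacts,
normalization pipelines, batch effects, RNA-seq count distributions,
non-Gaussian tails, and label noise from response-criteria ambiguity.
Passing tests on these cohorts therefore demonstrates correctness of the
machinery and behaviour under the assumed structure, not clinical
performance on real cohorts.

## Numerical choices and degenerate inputs

- All significance and t thresholds are strict inequalities; a gene with
  $t$ exactly 2 is not a primary marker.
- A zero-variance gene with zero mean difference gets $t = 0$, $p = 1$
  (uninformative, not an error); zero-variance genes in correlation
  matrices yield `NA` with a warning.
- Probe collapse defaults to the mean across probes (deterministic and
  symmetric); `max_var` keeps the most variable probe.
- Genes with any missing value are dropped at load time with a warning:
  every downstream computation assumes complete matrices.
- Sector membership uses closed arcs with a $10^{-12}$ angular tolerance;
  `in_region` at the origin is false whenever $r_\min > 0$.
- Evaluation percentages are rounded to integers (`round(100·correct/selected)`),
  matching the Selected/Correct presentation convention; undetermined
  samples are never counted as correct.

## Validation strategy and problem sizes

The test suite pairs every nontrivial computation with an independent
oracle: the closed-form projection against a numeric energy minimizer
(1000 random instances, tolerance $10^{-8}$), the unmoderated statistic
against the direct pooled-t formula ($10^{-10}$), the moment-matching
estimator against a stand-alone uniroot solution and against `limma`, BH
against hand-executed step-up vectors, sector membership against a
brute-force angle test, and the selection rule against a hand-enumerable
fixture in which each exclusion rule fires. Property tests cover partition
($n_\text{sens} + n_\text{res} + n_\text{und} = n$ under fuzzing),
monotone elimination (early calls invariant to later-step edits), training
floors holding by construction, and bit-reproducibility under fixed seeds.

The end-to-end benchmark fits cascades on 20 synthetic training cohorts of
$30+30$ samples (effect 1.5 SD, two resistant subtypes) and evaluates them
on independently drawn cohorts of the same design; these sizes mirror the
small clinical cohorts the method targets while keeping the full suite fast.
Under these conditions the fitted cascades typically call ~80–85% of
held-out samples correctly among ~75–85% called, abstaining on the rest;
accuracy is limited by the generator's deliberate factor confound rather
than by the search. `scripts/acceptance.R` recomputes these quantities
from scratch for any seed.

## Known limitations

- The exhaustive search is exponential in $k$ and pool size; it is
  intentionally capped rather than heuristically pruned.
- Purity 1.0 on small cohorts overfits: a region flush with the training
  data's class boundary loses several points of purity on held-out samples
  (the margin qualification recovers only part of this).
- Min–max normalization is sensitive to single outliers in the reference
  cohort; bounds are not robustified because the projection convention
  expects the full observed range.
- The two-stage selection rule assumes exactly three cohorts, as in the
  workflow it formalizes.
- No probabilistic calibration is attempted: the cascade's output is a
  call or an abstention, not a probability, and ROC-style machinery is
  out of scope by design.
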