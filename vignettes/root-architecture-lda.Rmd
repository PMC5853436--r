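---
title: "Discriminant analysis of seedling root system architecture"
author: "rootlda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant analysis of seedling root system architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootlda)
```

## The problem

Seedling root system architecture (RSA) — how many seminal roots a cereal
seedling grows, how long they are, how densely laterals branch from them,
how wide and deep the system spreads — is plastic and hard to summarise.
This package implements a pipeline for asking whether the *joint*
distribution of RSA traits differs between groups of plants, for example
between wheat lines classified as low or high nitrogen uptake efficiency
(NUpE) in field trials, and between low- and high-nitrate growth media.
Single traits typically show no usable correlation with such labels; the
signal, where it exists, sits in linear combinations of many traits.

The unit of data is one plant's 2-D root geometry: a set of polylines for
seminal roots (anchored at the seed) and lateral roots (attached to a
parent seminal at a known arc-length position), as produced by root-imaging
software or by this package's synthetic generator, exchanged via RSML
files.

## From geometry to variables

Eleven image-derived traits are computed per plant: total root length,
average seminal tip and emergence angles, average seminal and lateral root
lengths, lateral and seminal root counts, convex hull area, maximum width,
maximum depth, and the width–depth ratio. Coordinates follow the image
convention (y increases downward from the seed), so depth is positive and
all angles are measured from the downward vertical in degrees.

Two conventions deserve a note because published trait definitions leave
them open:

* **Angle window.** The emergence (tip) angle of a seminal root is the
  angle of the chord spanning its proximal (distal) 10% of arc length.
  A chord over a fixed arc-length fraction is stable against endpoint
  noise; the fraction is exposed as `angle_window`.
* **Standardization.** Columns are scaled to mean 0 and *sample* variance
  1 (divisor $N-1$), the common statistical convention.

Five further *shape coordinates* (`Geom1`–`Geom5`) come from a pairwise
distance between whole root systems followed by classical multidimensional
scaling:

* Both systems are re-anchored with the seed at the origin and every curve
  is resampled to $m = 50$ points equally spaced in arc length.
* The cost between two curves is the root-mean-square of the pointwise
  Euclidean gaps of the aligned samples.
* Seminal roots of the two plants are matched by a minimum-total-cost
  assignment (Hungarian algorithm); lateral sets are matched the same way;
  a curve left unmatched by a count difference pays its RMS distance to
  the degenerate curve at the origin.
* The distance is the seminal cost plus `lateral_weight` (default 1)
  times the lateral cost.

This construction is symmetric and translation-invariant by design, and it
deliberately **retains size**: a big and a small plant are far apart even
if similarly shaped, which is why `Geom1` typically correlates strongly
with total length. The triangle inequality is *not* guaranteed (optimal
assignment plus penalty terms can violate it), which is acceptable because
the distances feed an eigendecomposition, not a metric search structure.
Classical (Torgerson) scaling double-centres the squared distances and
eigendecomposes; negative eigenvalues (the non-Euclidean part) are dropped
and their mass reported. Each coordinate is flipped so its
largest-magnitude entry is positive — a deterministic sign rule applied
identically to MDS and PCA axes.

## The discriminant machinery

With $H$ the between-group and $E$ the within-group scatter of the
standardized $N \times p$ matrix, linear discriminant analysis solves the
generalized eigenproblem $H a = \lambda E a$ via the Cholesky whitening of
$E$, keeping $r = \min(p, g-1)$ discriminants. Each loading vector is
scaled so $a^\top S_w a = 1$ with $S_w = E/(N-g)$: scores then have
identity pooled within-class covariance, which is the convention under
which loading magnitudes are comparable across variables and across
studies. Scores are centred at the grand mean. Because eigenvector signs
are arbitrary, LD1 is oriented by a reference contrast (by default so the
low-NUpE group mean is negative) and remaining discriminants so the
largest-magnitude loading is positive.

Group separation on the full design (line × nitrate cells) is summarised
by Mahalanobis distances between cell means. With 16 variables and
cell sizes near 17, per-pair covariance pooling is unstable, so the
default pools the within-cell covariance across *all* cells ($N - G$
degrees of freedom); pair pooling remains available. Mean confidence
regions in a discriminant plane use the normal-theory ellipse
$\{\mu_g + u : u^\top (\hat\Sigma_g/n_g)^{-1} u \le \chi^2_2(\gamma)\}$
with per-group empirical score covariance, at $\gamma = 0.99$ by default.

### Variable selection, bootstrap, permutation

Subsets of variables are scored by
$$\zeta^2 = \frac{U}{U + r}, \qquad U = \mathrm{tr}(E_S^{-1} H_S),$$
the Hotelling–Lawley trace normalised into $[0,1]$; when $r=1$ it equals
the squared first canonical correlation $\lambda_1/(1+\lambda_1)$, an
identity the tests exploit as an oracle. `best_subsets()` enumerates every
subset of each size exhaustively (feasible through $p = 16$; ~65k subsets
take a few seconds) with lexicographic tie-breaking.

`bootstrap_loadings()` resamples plants with replacement, refits the LDA
per replicate, orders discriminants by eigenvalue and aligns each
replicate's sign with the full-data reference loading (eigenvalue-order
matching is a documented limitation when eigenvalues are near-degenerate).
Replicates that lose a group, or leave one with a single member, are
redrawn and counted. Reported per loading: the bootstrap mean, the
bootstrap standard deviation, and SE $= \mathrm{sd}/\sqrt{B}$; the
normal-approximation p-value $2\Phi(-|\mathrm{mean}|/\mathrm{SE})$ uses
the latter, the scale on which published loading tables print their
standard errors.

`permutation_test()` shuffles group labels uniformly within blocks —
all four groups; within NUpE classes; within nitrate levels; the crossed
pairing; or one NUpE class holding the other fixed — and recomputes
$\zeta^2$ of the full four-group labelling on a **fixed** variable subset.
The p-value uses the add-one estimator $(1 + \#\{\zeta^2_{perm} \ge
\zeta^2_{obs}\})/(1 + n_{perm})$ and so never returns 0. Fixing the subset
(selected once on the observed labels) is slightly anti-conservative
relative to re-selecting inside every permutation; re-selection is
available behind `reselect = TRUE` at roughly the cost of one exhaustive
search per permutation.

## The synthetic cohort generator

Real cohorts of this kind are imaging data; to make every stage testable
the package generates cohorts with known structure. The generator is a
*gravitropic correlated random walk*, not a biological growth model: its
only contract is to produce root systems whose trait distributions carry
planted group differences.

Each seminal root grows as a chain of 1 mm segments; at every step the
heading is pulled toward the downward vertical by a gravitropism weight
(default 0.18) and perturbed by Gaussian noise (sd 6° per step). Seminal
count is Poisson (mean 4.5, truncated at 1), seminal length log-normal
(median 150 mm, log-sd 0.25), emergence angles normal around 25° from
vertical. Laterals arise as a Poisson process (0.10 per mm) along each
seminal beyond a 15 mm basal offset, with log-normal lengths (median
10 mm) and branch angles around 60°. These magnitudes describe a
~9-day-old wheat seedling in a growth pouch.

The default *effect profile* mirrors the structure such experiments
report: the NUpE-class contrast is the large one (seminal length log-mean
+0.25 ≈ 1 within-group sd, lateral density +0.04 ≈ 2 sd of the lateral
count), the nitrate contrast is smaller, and smaller still within the
high-NUpE groups (+0.12 vs +0.05 on length log-mean). Nine lines carry
small fixed parameter tweaks and line-specific nitrate-response
multipliers (smallest for W145, largest for W705), and the high-nitrate
cell of line W199 is absent, giving 17 cells of 17 plants = 289 plants.
An `effect = "null"` spec removes every shift and line effect, for
calibration studies. One master seed drives everything; each plant draws
from a substream derived from the seed and the plant's index, so
generation order is irrelevant.

What the generator does **not** emulate: curvature patterns of real
roots, root interactions, measurement/segmentation error, heteroscedastic
trait noise, or any real line's actual phenotype. Tests passing on
synthetic cohorts therefore validate the *statistical machinery* —
recovery of planted effects at honest error rates — not biological claims
about wheat.

## Numerical choices and degenerate inputs

* Scatter solves go through the Cholesky factor of $E$; a singular $E$
  aborts with advice to select fewer variables rather than silently
  regularising.
* Subsets whose $E_S$ is singular are skipped (and counted) during
  search.
* A degenerate convex hull (fewer than three non-collinear points) has
  area 0, not an error; a zero maximum depth gives width–depth ratio 0.
* Mahalanobis distance between identical means is 0 even when the pooled
  covariance is singular.
* Ties in the percentile-exemplar search break by plant id; quantiles use
  linear interpolation (R type 7).
* RSML coordinates are written with six decimals, so files round-trip to
  10⁻⁶ mm and repeated writes are byte-identical.

## Problem sizes used by the test suite

The suite validates each operation against independent oracles at small
sizes (brute-force permutation enumeration for assignments, random-search
Rayleigh maximization for LD1, bitmask enumeration for subset search,
exact label enumeration for a 6-plant permutation test) and runs the
calibration studies at sizes chosen to keep the full suite down to a few
minutes: 200 label-independent datasets with 500
permutations each for the type-I error check, and 50 planted plus 50 null
default cohorts (289 plants each, traits only — the permutation statistic
there uses the 11 image-derived traits, since shape coordinates add
pairwise-distance cost without changing the planted-signal question) for
the power/calibration study. The acceptance script runs the full
16-variable pipeline, including distances and MDS for all 289 plants,
B = 1000 bootstrap replicates and 10 000 permutations per scheme.

## Known limitations

* The root-system distance compares laterals independently of their
  parents and ignores topology beyond the seminal/lateral split; a
  quotient-space tree metric would be the principled alternative and is
  out of scope here.
* Discriminant matching across bootstrap replicates is by eigenvalue
  order; near-degenerate eigenvalues can swap discriminants between
  replicates and inflate loading spread.
* Exhaustive subset search is exponential in $p$ and refuses $p > 20$.
* The normal-approximation loading p-values inherit the usual caveats of
  bootstrap normal intervals for strongly skewed loading distributions.
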