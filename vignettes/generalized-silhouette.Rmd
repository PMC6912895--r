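---
title: "Methods: the generalized silhouette width"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the generalized silhouette width}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gensil)
```

## The index and its assumptions

The silhouette width scores how well each object of a crisp, exhaustive
partition fits its cluster by contrasting cohesion with separation. For a
focal object $i$ in cluster $A$,

$$a(i) = M_p\big(\{d_{ij} : j \in A,\ j \neq i\}\big), \qquad
c(i, C) = M_p\big(\{d_{ij} : j \in C\}\big), \qquad
b(i) = \min_{C \neq A} c(i, C),$$

$$s(i) = \frac{b(i) - a(i)}{\max\big(a(i),\, b(i)\big)} \in [-1, 1],$$

where $M_p$ is the generalized (power/Hölder) mean,

$$M_p(x_1, \dots, x_n) = \Big(\tfrac{1}{n}\sum_k x_k^p\Big)^{1/p},$$

with the continuous limits $M_0 = (\prod_k x_k)^{1/n}$,
$M_{-\infty} = \min$, $M_{+\infty} = \max$. The only inputs are a
dissimilarity matrix (symmetric, nonnegative, zero diagonal — no metric or
distributional assumption) and a partition with $k \ge 2$ clusters. $p = 1$
is the classic arithmetic-mean silhouette. Because $M_p$ is nondecreasing in
$p$ for fixed nonnegative inputs, both $a(i)$ and $b(i)$ are nondecreasing in
$p$ object-by-object; $s(i)$ itself need not be monotone and the package
never assumes it is.

Interpretation of the exponent: low $p$ weights the smallest distances, so
the index rewards *connectedness* — each object sharing a cluster with its
nearest neighbours — and tolerates elongated, ring-shaped or otherwise
non-spherical clusters. High $p$ weights the largest distances, sharpening
the preference for *compact*, spherical clusters. At the extremes the index
applies the logic of single linkage ($p = -\infty$) and complete linkage
($p = +\infty$).

Two sample summaries are reported by `silhouette_summary()` and the sweep
drivers:

* **MSW** — the arithmetic mean of $s(i)$ over the sample. This stays
  arithmetic for every $p$: the generalization applies to the within/between
  *distance* averages only, not to the aggregation of widths.
* **MR** — the proportion of objects with $s(i)$ *strictly* below zero.
  Objects at exactly zero (including singleton-cluster objects) are not
  counted as misclassified but remain in both denominators; excluding
  singletons would silently inflate MSW for methods, like single linkage on
  noise, that shed many singletons.

## Parameters that matter

* `p` — the power-mean exponent, dimensionless, on the extended real line.
  Default 1 (classic silhouette). The default grid
  `default_p_grid()` $= \{-\infty, -3, -2, -1, 0, 1, 2, 3, +\infty\}$
  covers all the closed-form special cases (min, harmonic, geometric,
  arithmetic, quadratic, max) and is spread evenly near zero where the
  index changes fastest. Text serialization uses the tokens `"-inf"`/`"inf"`.
* `method`, `beta` — linkage rule for `agglomerate()`. The flexible rule
  uses the classic equal-weight Lance–Williams form
  $\alpha_i = \alpha_j = (1-\beta)/2$, $\gamma = 0$ (cluster sizes do not
  enter the weights; size-weighted "flexible UPGMA" variants exist but are
  not what the conventional flexible-beta method denotes). Default
  $\beta = -0.25$, the usual space-conserving choice.
* `k_range` — cut levels for `method_comparison()`, default `2:20`.
* Pattern-generator parameters (blob spread, strip geometry, ring radii,
  duplicate offset) are fixed defaults chosen to realize each archetype's
  qualitative description; see below.

## Distances and standardization

All built-in experiment drivers use Euclidean distances: on raw coordinates
for the synthetic archetypes, and on standardized variables for the Iris
example (mean 0, standard deviation 1 with the $n-1$ denominator — the
convention of `scale()`). Any other dissimilarity can be supplied directly
to `gen_silhouette()`, `silhouette_profile()` or `agglomerate()` as a `dist`
object, a full square matrix, or a lower-triangle file through the CLI.

## Numerical choices

* **Single code path.** Every finite nonzero $p$ uses the one defining
  formula; only $0$ and $\pm\infty$ are special-cased as their limits. No
  interpolation between special cases.
* **Overflow safety.** $x^p$ explodes as printed, so the implementation
  rescales by the sample extremum — maximum for $p > 0$, minimum for
  $p < 0$ — making every ratio term at most 1 in magnitude after
  exponentiation. Values up to $10^6$ with $|p|$ up to 100 stay finite;
  terms that underflow to zero are negligible by construction relative to
  the retained leading term.
* **Zeros.** Duplicate objects give zero distances, which sit on the
  boundary of the power mean's domain (positive reals). For $p > 0$ zeros
  enter the formula normally; for $p \le 0$ any zero forces $M_p = 0$ — the
  mathematical limit — which keeps the index defined on real data with
  ties. An object with $a = b = 0$ takes $s = 0$ (continuity with the
  "doubtful, between two clusters" reading of $s \approx 0$ rather than a
  0/0).
* **Convergence to the limits.** $M_p \to \max$ as $p \to \infty$ at the
  exact rate $n^{-1/p}$ when one element dominates, i.e. a relative deficit
  of about $\ln(n)/p$; at $|p| = 30$ and $n \approx 12$ that is still ~8%,
  so moderate exponents should not be read as proxies for min/max. The
  implementation returns the exact extremes at $p = \pm\infty$.
* **Tie-breaks.** When several clusters tie for $b(i)$, the neighbour with
  the smallest cluster label under canonical (sorted) ordering is reported;
  $s(i)$ is unaffected. In agglomeration, equal minimal dissimilarities are
  resolved toward the lexicographically smallest pair of cluster slots.
  Both rules exist purely for cross-platform determinism.
* **Merge search.** Agglomeration is the stored-matrix Lance–Williams
  algorithm (in C++ via Rcpp) with a per-row nearest-neighbour cache; the
  cache accelerates the minimum search without changing which pair a full
  scan would select, tie-breaks included. Single, average and complete
  linkage produce monotone height sequences; flexible beta at
  $\beta = -0.25$ sits exactly on the boundary
  $\alpha_i + \alpha_j + \beta = 1$ of the classical monotonicity
  condition, so only nestedness of cuts — not height monotonicity — is
  treated as guaranteed for it.
* **Cutting.** `cut_tree(tree, k)` undoes the last $k - 1$ merges and
  labels groups by first member appearance, matching `stats::cutree()`.

## What the synthetic patterns emulate

`generate_pattern()` builds nine seeded 2-D point sets (100 points each;
1,000 for `random_big`) that isolate separation, compactness and
connectedness: a structureless uniform square split by a bisector; two blobs
with a sparse transitional bridge; two distinct compact blobs; two strongly
overlapping blobs with tiny-offset duplicate pairs labelled either with
their partner (`offset_pairs_same`) or against it (`offset_pairs_diff`) on
*identical* coordinates for equal seeds, so the pair of patterns differs
only in local connectedness; two long parallel strips whose gap exceeds
their widths; well-separated blobs of 20 and 80 points with the small one
tighter; and a tight core inside an annulus whose along-ring
nearest-neighbour spacing is smaller than the ring–core gap (so at
$p = -\infty$ the ring coheres, while for $p \ge 1$ every ring object's
within-cluster mean spans the ring diameter and exceeds its mean distance
to the core, marking the whole annulus misclassified).

Defaults worth noting: the duplicate-pair offset is 1% of the blob standard
deviation — far below typical interpoint spacing, so at $p = -\infty$ each
duplicate's nearest neighbour is its partner by construction (with a small
seed-dependent failure probability from coincidentally close base points,
which is why the qualitative contracts are asserted across seeds rather
than per seed); the annulus uses jittered equal angles so its spacing bound
holds deterministically.

These generators emulate *geometry only*: low-dimensional, isotropic
Gaussian or uniform noise, exact label balance, no measurement error
structure, no high-dimensional concentration effects, no non-Euclidean
dissimilarities. Tests passing on them show the index behaves as designed
on the archetypal shapes; they do not certify behaviour on real
high-dimensional or mixed-type data.

## Problem sizes and determinism

The test suite evaluates: exhaustive brute-force agreement on all two-cluster
labelings for $n \in \{5, 8, 12\}$ against an independently coded direct
evaluator; classic-silhouette equivalence at $p = 1$ on 20 random datasets
($n \le 200$, $k \in 2..6$) against `cluster::silhouette()`; linkage heights
against `stats::hclust()` and `cluster::agnes()`; and the qualitative
archetype and method-comparison contracts on 10 independent seeds at the
design sizes (100-point archetypes; 1,000 points, $k = 2..20$ for the method
comparison, scored at $p \in \{-\infty, 1, +\infty\}$, the exponents whose
orderings are asserted). All randomness is seeded; pattern generation uses
an isolated RNG scope and never mutates the caller's random state.

## Known limitations and open directions

* Raw MSW/MR values at different $p$ span different ranges (widest at
  strongly negative $p$) and are not directly comparable across exponents;
  a principled comparison would standardize each against its expectation
  under a null model estimated by randomization. No such null-model
  procedure is implemented here — profiles should be read qualitatively,
  and no "optimal $p$" is nominated.
* Fuzzy-membership silhouettes, silhouette-driven reallocation and other
  validity indices (e.g. generalized Dunn) are out of scope, as are Ward,
  centroid/median linkage and non-hierarchical clustering.
* The flexible-beta variant is the equal-weight rule; size-weighted
  flexible variants would need their own Lance–Williams coefficients.
* `silhouette_profile()` recomputes from the full distance matrix per
  exponent; memory is $O(n^2)$, comfortable to a few thousand objects.
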