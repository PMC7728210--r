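---
title: "Hamming-distance clustering of chromatin accessibility peak sets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hamming-distance clustering of chromatin accessibility peak sets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PeakHamming)
```

## The problem and the model

ATAC-seq measures chromatin accessibility genome-wide, but read counts
depend strongly on library size and sequencing conditions, and the usual
fix — quantile normalization over merged target regions — assumes that
different cell types share a read-count distribution. **PeakHamming**
implements an alternative that avoids that assumption entirely: reduce
each sample to a *binary* genome and compare samples by exact
set differences.

The pipeline, per sample:

1. **Peak calling.** An external caller (MACS2
   `callpeak --nomodel --nolambda --keep-dup all -p pG`) produces peaks
   $g_k = (\gamma_k, \alpha_k, \beta_k)$ with p-values $p_k \le p_G$.
   Alignment, deduplication and MQ $\ge 30$ filtering are upstream
   prerequisites of the wrapper, not part of this package.
2. **Ranking and truncation.** Peaks are ordered by ascending p-value
   ($p_k \le p_{k'}$ for $k < k'$) and truncated at a rank threshold
   $M_{cut}$, discarding high-p peaks whose geometry is
   caller- and depth-dependent rather than biological.
3. **Binarization.** The binary sequence $B = \{h_{\gamma,x}\}$ sets
   $h_{\gamma,x} = 1$ exactly when some retained peak covers position
   $x$ of chromosome $\gamma$, at 1 bp resolution (no binning).
4. **Hamming distance.** Samples are compared by
   $H(B^{c_1}, B^{c_2}) = \sum_{\gamma,x}
   \delta(h^{c_1}_{\gamma,x}, h^{c_2}_{\gamma,x})$,
   the number of discordant positions.
5. **Clustering.** Agglomerative clustering with explicitly defined set
   distances — $H_{UPGMA}$ (mean pairwise distance) or $H_{Ward}$ (a
   quadratic within/between form; see below) — merging the minimum-distance
   pair at each step and recording the full historical cluster list
   $C_1, \dots, C_{2N_s - 1}$.
6. **Penalty.** Given known cell-type labels
   $S = \bigcup_\nu S_\nu$, the type penalty
   $\lambda_\nu = |C_{\tau(\nu)}| - |S_\nu|$ counts the foreign samples
   in the first (creation-order) cluster containing all of $S_\nu$; the
   global penalty $\lambda = \sum_\nu \lambda_\nu$ is the cost function.
   It is bounded by $0 \le \lambda \le (|\mathbb{T}|-1)\cdot|S|$ and
   vanishes exactly when every type is an offspring set of the
   dendrogram.
7. **Optimization.** $(M_{cut}, p_G)$ is chosen by grid search
   minimizing $\lambda$, with a plateau-midpoint rule when a run of
   $M_{cut}$ values ties at the minimum.
8. **Classification.** A new sample $\zeta$ is compared to each
   reference type by $H_{Ward}(\{\zeta\}, S_\nu)$; types are ranked
   ascending, and the rank gap $G_{T_0,\zeta} = q - 1$ quantifies
   disagreement with an expected type $T_0$.

The key modeling assumption is that the most significant peaks are the
reproducible, cell-type-informative ones, so discarding low-ranked peaks
*reduces* technical variance at an acceptable cost in signal — which is
exactly what the penalty optimization over $M_{cut}$ trades off.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| $p_G$ | caller significance ceiling | grid $10^{-1.5} \dots 10^{-4}$ | an exploratory $M_{cut}=\infty$ scan brackets the useful region |
| $M_{cut}$ | rank truncation (peaks) | grid, step 2000 | step matches the search resolution used on a 77-sample hematopoietic cohort |
| linkage | set-distance function | `ward` | lowest penalties in practice; `upgma`, `wpgma`, `upgmc`, `wpgmc` available |
| metric | track dissimilarity | `hamming` (bp) | exact integers; `dice` ($1-$Dice) exposed as an alternative |
| annotation window | peaks per window | 1000 (80 windows) | profiles the top 80000 peaks against a ChromHMM segmentation |
| downsampling $r$ | read removal fraction | user grid | removes exactly $\lceil r N_r \rceil$ reads, uniformly, seeded |

## Numerical conventions

**Coordinates.** Internal coordinates are 1-based inclusive
$[\alpha, \beta]$, matching the pointwise definition
$\alpha_k \le x \le \beta_k$; all BED-family I/O converts at the
boundary (0-based half-open), and a write/read round trip is the
identity. The reported *peak width* is $\beta - \alpha$ (a 1 bp peak has
width 0), while covered-length accounting everywhere uses
$\beta - \alpha + 1$; both are deliberate and tested.

**Interval algebra instead of vectors.** Binary tracks are stored as
disjoint, sorted, adjacency-merged intervals; a genome-length 0/1
vector (~3·10⁹ positions for a human genome) is never materialized.
The Hamming distance is computed by inclusion–exclusion,
$H = |a| + |b| - 2|a \cap b|$, which is provably identical to the
per-position XOR count — the test suite checks this against an explicit
bit-vector oracle on a toy genome. Distances stay exact integers until
linkage.

**The Ward height convention.** The quadratic Ward quantity
$$Q = \frac{D_{1,2}}{|C_1|+|C_2|}
  - \frac{|C_2| D_1}{|C_1|(|C_1|+|C_2|)}
  - \frac{|C_1| D_2}{|C_2|(|C_1|+|C_2|)}$$
is squared-distance-like (for singletons $Q = d^2/2$), while the
singleton prefactor convention $H(\{c_1\},\{c_2\}) = 2^{-1/2} d$ is
distance-like. These two statements are dimensionally incompatible, so
the package adopts $H_{Ward} = \sqrt{\max(Q, 0)}$ — which satisfies the
singleton identity exactly — and retains raw $Q$ in the merge records
(`rawQ`) for audit. Because $\sqrt{\cdot}$ is strictly increasing, merge
order, dendrogram topology and therefore all penalties are unaffected
by this choice.

**Fast path.** `agglomerate()` uses Lance–Williams recurrences (Ward
and the centroid methods on squared distances; UPGMA/WPGMA on raw
distances). For Ward and UPGMA this is algebraically equivalent to
re-evaluating the set formulas from the base matrix at every step; the
test suite verifies the equivalence (merge sequence and heights to
1e-10) on random matrices with $n \le 8$ against a direct-evaluation
oracle. WPGMA/UPGMC/WPGMC follow the textbook coefficients; centroid
heights are reported as $\sqrt{\max(\cdot,0)}$ of the squared-scale
value (which can be non-monotone, as is inherent to those methods).

**Tie-breaking.** The agglomeration step assumes a uniquely determined
minimum pair; to make the algorithm total we break ties by the
lexicographically smallest historical index pair $(\tau', \tau'')$, and
score ties in classification rankings alphabetically by type label.
Peak-score ties rank by genomic coordinate. All three rules exist for
one reason: determinism across runs and platforms.

**Degenerate inputs and conventions.** Set distances involving an empty
cluster are 0. The Dice coefficient of two empty tracks is an error
(undefined value), as is a distance matrix with duplicate sample ids, a
non-symmetric matrix, or $M_{cut} \le 0$. An empty type contributes
$\lambda_\nu = 0$. The annotation center rule
$\sigma \le (\alpha_k+\beta_k)/2 \le \epsilon$ is evaluated as the exact
integer comparison $2\sigma \le \alpha_k+\beta_k \le 2\epsilon$,
boundary-inclusive, so half-integer centers need no rounding
convention. Annotation fractions always use the full window size as the
denominator, and windows extending past the available peaks are
dropped.

## Open design choices

- **Plateau midpoint.** An even-length minimizing run returns the lower
  median; non-contiguous minimizers reduce to the longest run, first
  run on ties. Among $p_G$ values tying at the global minimum, the one
  with the longest $M_{cut}$ plateau is selected (a flat optimum is
  preferred as more stable).
- **Downsampling scope.** Whether read loss should be simulated per
  sample or cohort-wide is ambiguous; `robustnessCurve()` downsamples
  all samples simultaneously within a replicate (with per-sample
  seeds), since cohort-wide loss is the pessimistic case. Per-sample
  curves can be obtained by passing singleton cohorts.
- **Downsampling position.** Reads are removed from the final
  analysis-ready read set (post-dedup); applying it earlier would
  entangle the removal fraction with duplicate structure.
- **Query handling.** Query samples are never added to the reference
  sets; each query is classified independently, and only the $N_{ref}$
  query-to-reference distances are computed per query (the incremental
  contract that makes adding samples cheap).

## The synthetic cohort generator

`simulateCohort()` exists so that every pipeline stage is testable
hermetically. It emulates the structure the method relies on: each cell
type has an archetype of `kInfo` non-overlapping informative peaks
(a fraction shared between types, the rest type-specific), each sample
is a jittered copy of its archetype plus `kNoise` sample-specific noise
peaks, and informative $-\log_{10} p$ scores strictly exceed noise
scores by a margin. Consequently truncation at $M_{cut} =$ `kInfo`
provably removes exactly the noise, within-type distances collapse to
jitter scale, and the planted clustering is recovered with
$\lambda = 0$ — the property the parameter-recovery and classification
tests assert.

Defaults were chosen once, as a realistic miniature: 2 chromosomes ×
150 kb (sized so that $3 \times 300$ archetype peaks at ~280 bp spacing
fit without overlap), 3 types × 4 samples, `kInfo = 300`,
`kNoise = 200`, peak widths $\mathcal{N}(150, 30^2)$ bp clamped,
informative scores uniform on $[20, 100]$ versus noise on $[2, 10]$,
and 10 bp positional jitter. The toy read simulator places reads so
expected pileup is flat across a peak, and `toyPeakCaller()` calls
maximal pileup runs above a threshold with a monotone score floored at
$-\log_{10} p_G$ — it honors the external-caller contract but makes no
claim of MACS2 fidelity.

What the generator does *not* emulate: Tn5 insertion bias, fragment
length structure, GC effects, p-value splitting/merging of peaks across
$p_G$ (real callers can split one $10^{-2}$ peak into two at
$10^{-4}$), chromosome-scale coverage heterogeneity, or realistic
genome size. Passing tests therefore demonstrate algorithmic
correctness and the planted-structure recovery properties — not
performance on real cohorts, whose headline penalties require
genome-scale data and an external caller.

## Problem sizes used by the checks

The test suite and examples run at deliberately small scale, chosen as
the package's own test design: toy genomes of 30–300 kb, cohorts of
6–12 samples, oracle comparisons on $\ge 200$ random track pairs (50 kb
genome) and 100 random linkage instances ($n \le 8$), grid searches
over $M_{cut} \in \{100, \dots, 600\}$, and 100 held-out
classification trials. All randomness is seeded; generator seeds are
fixed in the specs that define each experiment.

## Known limitations

- The historical-list penalty search is linear in the number of
  clusters per type; for very large cohorts a bitset representation
  would be preferable.
- `upgmc`/`wpgmc` heights can invert (standard for centroid methods);
  penalties remain well-defined since they ignore heights.
- The MACS2 wrapper shells out and is only as reproducible as the
  installed caller; the package pins its flags but not its version.
- Hamming distances weight every base pair equally; no attempt is made
  to weight by annotation or mappability.
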