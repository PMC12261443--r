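---
title: "Selecting proximal regulators: the model behind gripnet"
author: "gripnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting proximal regulators: the model behind gripnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gripnet)
```

## The problem

Transcription of a target gene (TG) is controlled by transcription factors
(TFs) that bind regulatory DNA near the gene. In eukaryotes these TFs do not
act alone: activators, mediators, and the basal machinery must come into
physical contact, so the TFs that jointly regulate one gene tend to lie close
to each other in the physical protein-protein interaction (PPI) network.
Expression-based regulator inference ignores this constraint and happily
returns sets of TFs that could never assemble. `gripnet` selects, for each
TG, a small set of candidate TFs whose expression explains the TG's
expression *and* which are mutually close in the PPI network.

## The model

For one TG let $y \in \mathbb{R}^m$ be its (centered) expression over $m$
cells and $X = [x_1, \dots, x_n] \in \mathbb{R}^{m \times n}$ the
(column-standardized) expression of $n$ candidate TFs. The starting point is
L0-constrained ridge regression,

$$\min_{\|\beta\|_0 \le k} \; \|y - X\beta\|_2^2 + \rho\|\beta\|_2^2 ,$$

which is equivalent to a Boolean program over selector variables
$u \in \{0,1\}^n$ ($u_i = 1$ iff TF $i$ is selected): partially minimizing
over $\beta$ on a fixed support gives

$$\min_{u \in \{0,1\}^n,\ \sum_i u_i \le k} \;
  y^\top \Big(\tfrac{1}{\rho} X D(u) X^\top + I\Big)^{-1} y ,$$

with $D(u) = \mathrm{diag}(u)$. The test suite verifies this equivalence
numerically against the closed-form ridge solution on random instances
(`ridge_oracle`). Network proximity enters as a quadratic penalty on the
pairwise distances of the selected TFs:

$$G(u) \;=\; y^\top M(u)\, y \;+\; \lambda\, u^\top S\, u,
  \qquad M(u) = \Big(\tfrac{1}{\rho} X D(u) X^\top + I\Big)^{-1},$$

where $S_{ij}$ is the diffusion state distance (DSD) between TFs $i$ and $j$
in the PPI network and $\lambda \ge 0$ trades fit against proximity.

**Why DSD and not shortest paths.** Hop counts on PPI networks are coarse
(almost everything is 1-3 hops apart) and noisy (one spurious edge creates a
shortcut). DSD embeds each protein as the vector of expected $t$-step
random-walk visit counts, $He^t(v) = \sum_{i=0}^{t} e_v^\top P^i$ with $P$
the degree-normalized adjacency, and takes L1 distances between embeddings.
Being an L1 distance between vectors it is symmetric, non-negative and obeys
the triangle inequality by construction; the test suite checks all three
exhaustively on random graphs. The walk horizon defaults to $t = 7$ steps,
with a `converged = TRUE` variant that takes the infinite-horizon limit
$\|(e_u - e_v)^\top(I - P + W)^{-1}\|_1$ ($W$ carrying the stationary
distribution in every row); finite-horizon distances approach this limit as
$t$ grows, which is also under test. DSD is computed on the largest connected
component, since random-walk distances across components are undefined; TFs
outside it are handled by an explicit `missing_policy` (error, drop and
report, or fill with the largest observed distance).

**A caveat on curvature.** Distance matrices are not positive semidefinite
in general, so $u^\top S u$ need not be convex, whatever the provenance of
$S$. We do not pretend otherwise: `s_min_eigenvalue()` reports the smallest
eigenvalue of $S$, and `regulation_problem(..., s_shift = )` offers an
optional diagonal shift for users who want a certified-convex penalty at the
cost of modifying it. The default leaves $S$ untouched; the consequences for
the relaxation are discussed below, because they are visible in practice.

## Relaxation, solver, certificate, rounding

The Boolean program is relaxed to the capped simplex
$\{u : \sum_i u_i \le k,\ 0 \le u_i \le 1\}$. Minimizing $G$ there is a
smooth bound-constrained problem; we solve it by a projected quasi-Newton
iteration in which each candidate step is pushed through the exact Euclidean
projection onto the capped simplex and accepted under an Armijo
sufficient-decrease test, so accepted objectives are monotonically
non-increasing.

* **Projection.** The projection is computed exactly: if clipping to the box
  already satisfies the budget that is the answer; otherwise a threshold
  $\theta > 0$ with $\sum_i \mathrm{clip}(v_i - \theta, 0, 1) = k$ is located
  by sorting the $2n$ breakpoints of the piecewise-linear budget function
  ($O(n \log n)$) and solving the active segment in closed form. Tests
  compare it against both a bisection oracle and, for small $n$, exhaustive
  KKT-pattern enumeration.
* **Directions.** The fit term's Hessian has the closed form
  $\tfrac{2}{\rho^2}(cc^\top) \odot (X^\top M X)$ with $c = X^\top M y$
  (positive semidefinite by the Schur product theorem), so for the candidate
  counts this problem meets in practice ($n$ in the tens to hundreds) exact
  curvature is affordable. Each iteration first tries an active-set
  ("two-metric") Newton direction -- coordinates pressed against their bound
  by the gradient move along the gradient; the free block takes a Newton
  step with the budget constraint eliminated through its multiplier -- then
  a limited-memory L-BFGS direction, then a Barzilai-Borwein-scaled
  projected gradient step. We began with the plain projected L-BFGS/BB
  combination; on default-size instances it stalled near the boundary with
  projected gradients around $10^{-4}$ after hundreds of iterations, which
  is why the exact-curvature direction is tried first (`newton_limit`
  controls the cutoff; above it only the limited-memory directions run).
* **Stopping.** Convergence is declared when the projected-gradient step
  $\|u - P(u - \nabla G)\|_\infty$ falls below `grad_tol` ($10^{-6}$), or
  when progress has become numerically negligible (the decrease over the
  last 15 accepted steps below $10^{-5}$ of the total decrease) while that
  norm is already below $\sqrt{\texttt{grad\_tol}}$. The second clause
  matters on degenerate flat faces: a block of near-collinear candidates
  (e.g. several TFs with almost identical expression) makes the optimum a
  face, not a point, and first-order steps wander along it redistributing
  selector mass without changing the rounded support.
* **Everything in $n$-space.** All solver quantities are evaluated through
  the Woodbury identity
  $M = I - \tfrac{1}{\rho} X D^{1/2} (I + \tfrac{1}{\rho} D^{1/2} X^\top X
  D^{1/2})^{-1} D^{1/2} X^\top$ (the $D^{1/2}$ form keeps it valid for
  fractional $u$), so after one precomputation of $X^\top X$ and
  $X^\top y$ an iteration costs $O(n^3)$ independent of the cell count $m$.
  The direct $m \times m$ inversion is kept as a reference path and the two
  are compared entrywise to $10^{-10}$ in the tests.

**Exactness certificate.** The relaxation is exact -- its optimum Boolean --
precisely when a threshold separates the selection scores
$v_i = (x_i^\top M y)^2 + 2\lambda \sum_j S_{ij} u_j$ of the supported
coordinates from the rest. `check_tightness()` evaluates the scores at the
computed solution, takes the support as $\{i : \hat u_i > 10^{-4}\}$
(numerical solutions are never exactly Boolean), and reports the separating
interval. Two implementation choices deserve a note. First, the matrix $M$
inside the scores is evaluated at the computed $\hat u$; the underlying
statement evaluates it at the exact optimum, which is unavailable. Second,
we additionally require the support to be no larger than the budget $k$:
a fractional solution with two exactly tied scores straddling the budget
(construct one by duplicating a column with $k = 1$) produces a
$(k{+}1)$-sized, perfectly separated support that must not be certified, and
the support of a Boolean optimum can never exceed $k$. The acceptance suite
backs every issued certificate by exhaustive enumeration.

**Rounding.** When the solution is fractional, Boolean candidates are drawn
coordinate-wise as $\tilde u_i \sim \mathrm{Bernoulli}(\hat u_i)$; draws
over budget are repaired by keeping the $k$ drawn coordinates with the
largest $\hat u_i$ (rejection can stall when $\sum \hat u \approx k$), the
deterministic top-$k$ candidate is always added to the pool, and the
feasible candidate with the smallest $G$ wins. The pre-repair draws are
unbiased for $\hat u$, which is under test at 10,000 draws.

## Candidate assembly and evaluation

Genomic preparation follows fixed region conventions: a peak overlapping the
strand-aware 500 bp window immediately upstream of the TSS is a *promoter*
peak; any other peak within 250 kb of the TSS on the same chromosome is a
*distal* candidate region; promoter takes precedence, so the classes
partition the in-window peaks. Overlap of a single base suffices (ATAC peaks
and annotation intervals never align exactly). All files use BED conventions
(0-based, half-open); in memory, regions are ordinary `GRanges` and the
conversion happens once at the I/O boundary. Candidate TFs are those with at
least one motif hit (produced upstream by a motif scanner; scanning is not
this package's job) in the promoter or distal regions -- promoter hits are
included by default because cooperating TFs bind both compartments, with
`include_promoter = FALSE` to restrict. `assemble_problem()` centers $y$,
standardizes the columns of $X$ (dropping zero-variance candidates with a
warning), and slices $S$ so that TF order is identical across $X$ and $S$.
Standardization lives here, not in the optimizer, so the model always sees
comparable scales regardless of upstream normalization.

Three benchmark metrics mirror how such inferences are evaluated:

* **Out-of-sample MSE** of a deliberately small feed-forward predictor
  (layer widths: number of TFs, 20, 1; logistic hidden units, linear
  output) fit on 90% of cells and scored on the held-out 10%. Only the layer
  widths are fixed by convention; activation, weight decay ($10^{-4}$) and
  epoch budget (200) are explicit arguments. The fit is `nnet` under a local
  seed, so identical seeds give identical splits and weights.
* **Average TF distance**: the mean pairwise DSD between the inferred TFs.
* **F1 against promoter-capture links**: with $\Omega$ the unique candidate
  regions hit by the top-$k$ inferred TFs, $\Lambda$ the regions linked to
  the TG's promoter by promoter-capture interaction data, and
  $\Delta \subseteq \Omega$ those overlapping $\Lambda$, precision is
  $|\Delta|/|\Omega|$, recall $|\Delta|/|\Lambda|$, and F1 their harmonic
  mean (0 when undefined). $\Omega$ is restricted to the TG's own candidate
  regions by default; a region hit by several TFs counts once. $k = 3$ is
  the primary variant, $k = 5$ secondary.

Hyper-parameters $(\rho, \lambda, k)$ are selected by $k$-fold
cross-validation (`cross_validate`): per grid point and fold, the selector
is fit on the training cells and scored by the held-out MSE of a closed-form
ridge refit on the selected support. Ties break toward smaller $k$, then
smaller $\lambda$, then smaller $\rho$ -- the least complex model. Fold-level
fits run under a bounded iteration budget and a loosened gradient tolerance
($10^{-4}$), and walk the $\lambda$ grid from large to small with warm
starts: the CV score depends only on the selected support, which settles
long before the fractional selector is polished.

## The synthetic study

Everything above is exercised on synthetic instances built by
`generate_instance()`, which emulates the full input stack: a PPI graph over
the candidate TFs with the true regulators planted as a clique, expression
from the linear model $y = X\beta^* + \varepsilon$, and toy
peak/motif-hit/link tables wired so that the true TFs' peaks are exactly the
promoter-linked regions. Defaults: $n = 30$ TFs, $m = 200$ cells, $k^* = 3$
true regulators, $\sigma = 0.5$ noise, Erdős–Rényi graphs at $p = 0.15$
(disconnected draws are repaired by one random bridging edge per extra
component, keeping the density essentially unchanged). $\beta^*$ is graded
(`seq(1, 0.5)`) because real regulators differ in strength, and the
identity of the weakest one is exactly what a confounder attacks.

**Decoys.** A decoy is a candidate TF whose expression tracks the TG's
*regulatory signal* $X\beta^*$ (correlation 0.98 by default) but which sits
far from the true regulators in the network (at least 4 hops; each decoy is
a pendant on its own far-lobe anchor, so decoys are also mutually scattered
-- a mutually adjacent decoy block would itself be a planted proximal set,
which is the opposite of a confounder). Correlating decoys with the
noise-free signal rather than with the realized $y$ is a deliberate choice:
it models co-expression through a shared upstream program, and a decoy
correlated with the realized $y$ would carry information about the noise
$\varepsilon$ in every cell, making it a genuinely better predictor that no
honest prediction-based model selection could be expected to reject. The
0.98 default puts the decoys where expression alone barely distinguishes
them from the true regulators -- the regime the proximity term exists for.

**What the study shows, and what it honestly does not.** The planted
proximity hypothesis is recovered: pooled within-regulon distances test
significantly smaller than background distances (median one-sided
Mann-Whitney $p < 0.05$ over seeds), and regulons drawn from the background
give null-like $p$-values. Degree-preserving randomization of the network
(seeded double-edge swaps, $10 \times |E|$) never improves recovery. But the
per-instance ablation of $\lambda$ is sobering: on decoy instances where
the pure sparse model ($\lambda = 0$) fails, it usually fails because the
*relaxation* is loose -- fractional selector mass rides the block of
mutually correlated decoys at low proximity cost, the certificate correctly
reports non-exactness, and rounding from that fractional solution cannot
reach the true clique; large $\lambda$ does not rescue it, because
$u^\top S u$ grows with the square of the support size, so a heavily
weighted proximity term prefers *smaller* supports (ultimately singletons,
which pay no pairwise penalty at all) over equally-sized proximal ones, and
mixed true/decoy supports -- the natural stepping stones -- carry the
largest penalties of all, forming an energy barrier between the decoy and
clique modes. Cross-validated $\lambda$ therefore improves recovery on some
decoy instances and harms it on a comparable number; users should read the
exactness certificate, not assume the proximity term fixes identifiability.
The acceptance suite asserts the optimistic version of this claim and we
leave it failing rather than weaken it; the numbers behind the statement are
recomputed by `scripts/acceptance.R` on every run.

**Problem sizes under test.** Enumeration-backed checks run at
$n \le 12$, $k \le 3$, $m \le 60$ (100 instances); the ablation runs 50
instances at generator defaults; predictor benchmarks use $n = 12$,
$m = 80$ over 100 seeds. These sizes make every expectation checkable by
brute force or repetition while exercising the same code paths as full-size
problems.

**What the generator does not emulate.** Counts are Gaussian, not negative
binomial; there is no dropout, no library-size variation, no doublets; the
PPI graph is a small random graph, not a scale-free interactome; motif hits
are noiseless. Passing tests demonstrate correctness of the machinery and
the qualitative behavior of the model under its own assumptions -- they do
not certify performance on real scMultiome data.

## Numerical choices and degenerate inputs

* Ties in the top-$k$ rounding candidate and in `brute_force_oracle` break
  by index order (lexicographic), making every path deterministic.
* `mann_whitney_u` uses midranks and the tie-corrected normal variance, and
  switches to the exact permutation distribution for small tie-free samples
  ($n_a + n_b \le 10$); identical samples give $z = 0$, $p = 0.5$; an
  all-tied pooled sample is refused as degenerate.
* Zero-variance expression columns are dropped (with a warning) before
  standardization would divide by zero.
* A selector exactly at a bound with an outward gradient is held by the
  projection; the two-metric direction treats coordinates within
  $\min(10^{-3}, \|pg\|)$ of a bound as active.
* All randomness (rounding draws, CV folds, generators, network rewiring)
  flows from one integer seed through a deterministic fan-out; RNG state is
  restored after every internal use, so library calls never perturb the
  caller's random stream.

## Known limitations

The proximity penalty's quadratic growth in support size biases
$\lambda$-heavy fits toward small supports; a size-normalized penalty
($u^\top S u / \binom{\|u\|_1}{2}$, say) would decouple compactness from
cardinality but is no longer a quadratic form, and we keep the model as
formulated. The relaxation is provably exact only when the certificate
holds; on correlated candidate blocks it often does not, and the rounded
solution can then be several percent above the Boolean optimum. Each TG is
solved independently; there is no sharing of selections across TGs, no
directionality, and no attempt to distinguish activation from repression.
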