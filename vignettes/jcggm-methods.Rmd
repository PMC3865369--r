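---
title: "Joint conditional Gaussian graphical models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint conditional Gaussian graphical models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jcggm)
```

## The model

In a genetical-genomics study the expression of $p$ genes is measured in
$T$ conditions (tissues) on the same genotyped individuals. For condition
$t$ we assume

$$ Y^{(t)} \sim N_p\!\left(f^{(t)}(X),\ (\Omega^{(t)})^{-1}\right), $$

where $X$ is a $q$-vector of genetic markers (backcross coding 0/1) and
$f^{(t)}$ is an arbitrary condition-specific regression function. The
scientific object is the set of precision matrices $\Omega^{(t)}$: a zero
entry $\omega^{(t)}_{jj'} = 0$ means genes $j$ and $j'$ are conditionally
independent given all other genes *and* the markers. Conditioning matters
because a marker that drives many genes (an eQTL hotspot) induces marginal
correlations that an unconditional graphical model mistakes for gene-gene
edges.

Estimation is two-stage.

**Stage 1 — conditional covariance.** For each condition we estimate
$\Sigma^{(t)} = \mathrm{Var}(Y^{(t)} \mid X)$ with the reproducing-kernel
estimator

$$ \hat\Sigma^{(t)} = \tfrac1n\left( \mathbf{Y}^T Q \mathbf{Y} -
   \mathbf{Y}^T Q (QKQ)(QKQ)^\dagger Q \mathbf{Y} \right), \qquad
   Q = I_n - \tfrac1n J_n, $$

where $K$ is the covariate Gram matrix and $\dagger$ the Moore-Penrose
pseudoinverse. $(QKQ)(QKQ)^\dagger$ is the orthogonal projector onto the
column space of the centered kernel, so with a linear kernel this reduces
exactly to $S_{YY} - S_{YX} S_{XX}^\dagger S_{XY}$ on mean-centered data
(`linear_cond_cov()`), and with $q = 0$ covariates to the plain sample
covariance — the unconditional model is the degenerate case of the same
pipeline. For 0/1 backcross genotypes the linear kernel is the natural
choice (the regression function on a two-level genotype is automatically
linear); RBF and polynomial kernels are available for covariates where a
flexible $f$ is warranted.

Two numerical conventions used throughout: all moment matrices are computed
from mean-centered $Y$ and $X$ with divisor $n$ (the general kernel formula
centers through $Q$; centering the linear closed form as well makes the two
agree to machine precision, and expression data are never mean zero), and
pseudoinverses truncate singular values below $10^{-10}$ of the largest.
When $n \le q$ the conditional covariance is singular — the covariates can
interpolate the data — and the package warns; what happens to the
downstream fit in that regime is examined below.

**Stage 2 — joint sparse estimation.** The penalized profiled likelihood

$$ \mathrm{PPL} = \sum_{t=1}^T n_t\left(-\log\det\Omega^{(t)} +
   \mathrm{tr}(\hat\Sigma^{(t)}\Omega^{(t)})\right) +
   \lambda P(\{\Omega^{(t)}\}) $$

couples the conditions through a truncated-log penalty on the per-pair
magnitude sums $a_{jj'} = \sum_t |\omega^{(t)}_{jj'}|$:

$$ P = \sum_{j \neq j'} \begin{cases}
   \log a_{jj'} - \log\epsilon + 1, & a_{jj'} > \epsilon \\
   a_{jj'} / \epsilon, & a_{jj'} \le \epsilon .
   \end{cases} $$

Below $\epsilon$ (default $10^{-3}$) the penalty is a steep lasso of slope
$1/\epsilon$; above, it grows only logarithmically. An edge that is well
supported in one condition therefore makes the same edge cheap in all
others — the mechanism that borrows strength across tissues — while pairs
with no support anywhere are pushed hard to zero. The two branches meet at
value 1, so the penalty is continuous and concave in $a$.

## Optimization

The concavity of $P$ in the magnitude sums makes local linear approximation
(LLA) a majorize-minimize scheme: at iteration $k$ the penalty is replaced
by its tangent, giving per-pair weights

$$ \zeta^{(k)}_{jj'} = \frac{1}{\max\left(\sum_t
   |\omega^{(t),(k)}_{jj'}|,\ \epsilon\right)} $$

and decoupling the problem into $T$ weighted graphical lassos
$$\min_{\Omega \succ 0}\ \mathrm{tr}(\hat\Sigma^{(t)}\Omega) -
\log\det\Omega + \tfrac{\lambda}{n_t}\sum_{j\neq j'}\zeta_{jj'}
|\omega_{jj'}|$$ (the $1/n_t$ normalization is the same subproblem after
dividing by the sample size; it keeps the inner solver's conventions
uniform across conditions). Each accepted LLA step can only decrease the
PPL; the package records the objective path and asserts monotonicity in its
test suite.

The inner solver (`solve_wglasso()`) is a primal block-coordinate descent
on the columns of $\Omega$ with element-wise penalties, written in C++.
Each column update solves an $\ell_1$-penalized quadratic by coordinate
descent with an active-set strategy (full passes establish the support,
then passes cycle over the nonzeros until convergence, finishing with a
verification pass). We work in the primal rather than Friedman's
covariance-space algorithm because the primal iterate stays positive
definite throughout — important here, since the subproblem is handed
singular covariances in the small-sample conditional regime. With positive
off-diagonal penalty weights and a positive diagonal of $S$ the objective
is bounded below even for singular $S$, but its minimizer can be enormous;
the solver's sweep cap bounds the effort spent there (see "Degenerate
regimes"). Optimality of converged solutions is certified by the KKT
residual (`kkt_residual()`) and, in the tests, by agreement with an
independent ADMM solver.

Initialization follows the ridge rule: $\Omega_0^{(t)} = (\hat\Sigma^{(t)}
+ k\,\delta I)^{-1}$ with $\delta = 10^{-3}$ added repeatedly until the
eigenvalue condition number is at most $10^3$. The LLA stops when the
largest relative Frobenius change across conditions falls below $10^{-4}$
(cap 50 iterations). Because the penalty is nonconvex the procedure is
only guaranteed a local solution; the objective path is exposed and the
initializer is configurable, but no multi-start is attempted by default.

## Tuning

$\lambda$ is chosen by BIC,

$$ \mathrm{BIC}(\lambda) = \sum_t \left\{ -\log\det\hat\Omega^{(t)} +
   \mathrm{tr}(\hat\Sigma^{(t)}\hat\Omega^{(t)}) +
   \frac{\log(n_t)\, \mathrm{df}_t}{n_t} \right\}, $$

with $\mathrm{df}_t$ the number of upper-triangle entries (diagonal
included) larger than $10^{-6}$ in magnitude — the same threshold used to
declare edges, chosen far below the $\mathrm{Unif}(0.5, 1)$ scale of
simulated signals since the solver's zeros are exact but LLA re-weighting
can leave tiny residual values.

The default grid is 30 log-spaced values spanning a $10^5$ range downward
from $\lambda_{\max}$, the soft-threshold bound that zeroes every edge at
the first LLA iteration *given the actual initializer*:
$\lambda_{\max} = \max_t n_t \max_{j\neq j'} |\hat\Sigma^{(t)}_{jj'}|
\max(a_{jj'}, \epsilon)$ with $a$ from the ridge initializer. (A bound
computed for cap weights $\zeta = 1/\epsilon$, i.e. pretending the
previous iterate were zero, would be far too small: starting from the
dense ridge inverse, the first-iteration weights are $1/a_{jj'}$, and at
such small $\lambda$ nothing is ever zeroed — the path would degenerate to
uniformly dense fits.) Fits are warm-started down the grid, each from the
previous solution, so the path sweeps from the empty graph toward the
dense one; ties in BIC go to the larger $\lambda$. Since the BIC path is
empirically U-shaped in $\lambda$, the descent stops after six consecutive
grid points above the running minimum (`bic_patience`), which avoids
fitting the expensive dense tail; ROC construction (`roc_path()`)
disables this and fits the full grid.

## The simulation engine

The benchmark emulates a backcross genetical-genomics study: $T = 3$
conditions, $p = 30$ genes, $q = 10$ markers equally spaced on a single
1000 cM chromosome, sample sizes 30 and 100. Genotypes follow a Markov
chain along the chromosome with Haldane recombination fractions
$r = (1 - e^{-2d/100})/2$; at the default spacing ($\approx 111$ cM,
$r \approx 0.45$) markers are nearly independent.

The common network is grown by preferential attachment: a 7-node path
seeds the graph with 6 edges, and each further node attaches one edge to
an existing node with probability proportional to degree, giving
$M = 29$ common edges at $p = 30$; each condition then receives
$\mathrm{round}(0.1M) = 3$ extra edges drawn uniformly from the remaining
non-edges. Expression data are $Y^{(t)} = X B^{(t)T} + E^{(t)}$ with rows
of $E^{(t)}$ drawn $N_p(0, \Omega^{(t)-1})$. Case 1 gives each condition
three isolated marker effects (genes 1, 2, 3 driven by markers 1, 4, 8
with fixed coefficients); Case 2 is the hotspot design, where gene blocks
1-18, 19-25 and 26-30 load on markers 1, 4 and 8 with the Case-1
coefficients perturbed by $N(0, 0.1^2)$ — there, marker-induced marginal
correlation confounds unconditional network inference. The genotype draw,
network, precisions and noise are redrawn each replicate; the map is
fixed; one master seed drives the whole stream.

### Precision-matrix construction

Given a condition's adjacency, edge values are drawn from
$\mathrm{Unif}([-1,-0.5]\cup[0.5,1])$. For the diagonal, the package's
default (`build_precision(method = "rownorm")`) follows the row-normalized
construction standard in the multiple-graphical-model simulation
literature: divide row $i$ by $1.5 \sum_k |\omega_{ik}|$, symmetrize by
averaging with the transpose, and set the diagonal to 1. On hub-heavy
graphs the averaging can push the smallest eigenvalue slightly below zero
(a hub row inherits $|\omega_{ij}|/r_j$ terms from low-degree neighbors),
so a safeguard rescales the off-diagonal entries by a common factor
whenever the smallest eigenvalue falls below 0.05, restoring exactly that
margin. The support always equals the adjacency, and the resulting partial
correlations are moderate — recovering the graph at $n \in \{30, 100\}$ is
genuinely hard, which is the regime the benchmark is meant to probe.

An alternative construction (`method = "dominant"`) sets the diagonal to
the absolute row sum, $\omega_{ii} = \sum_{j\ne i} |\omega_{ij}|$, and
redraws until the matrix is positive definite. We do not use it for the
benchmark, for a structural reason worth recording: with equality diagonal
dominance the quadratic form of the $\pm1$ vector chosen sign-consistently
along edges collapses to zero on any cycle-free graph, so on trees this
matrix is *exactly singular* — and a preferential-attachment graph grown
one edge per node from a path seed is a tree. The per-condition graphs
(tree plus three extra edges) escape exact singularity but remain
near-singular, with two consequences: the rejection loop can never succeed
on tree-like structures, and where it does succeed the implied covariance
has an enormous dominant eigenvalue and extreme partial correlations
(leaf-leaf edges approach $\pm 1$), making support recovery nearly trivial
at $n = 100$ — the opposite of the benchmark's intent. The `"dominant"`
construction is retained for completeness and raises a clear error when
its rejection loop exhausts.

### What the generator does and does not emulate

The generator reproduces the study design — backcross linkage, scale-free
topology, shared-plus-specific edge structure, hotspot confounding — but
not several features of real expression data: non-Gaussian and
heavy-tailed noise, batch and environmental covariates, measurement error
correlated across tissues, and marker sets far larger than the sample
size. Passing the benchmark therefore demonstrates correct and competitive
behavior under the stated generative model, not performance guarantees on
real data.

## Degenerate regimes

At $n = 30$ with $p = 30$ genes and $q = 10$ covariates the conditional
covariance has rank at most $n - 1 - q = 19 < p$. For the separately
fitted conditional baseline the BIC then chases the unbounded likelihood
of near-singular fits down the penalty path and selects an estimate that
is dense (false-positive rate near 1) with enormous entries — the
well-known collapse of unregularized-by-joint-information conditional
fits, visible in the benchmark as a relative Frobenius loss in the
thousands. The reported magnitude of that loss is not a meaningful
quantity: it depends on how long the solver is allowed to chase the
divergence (the sweep cap, default 50 for `fit_separate_glasso()`). The
false-positive collapse itself is robust. The joint fit under the same
degeneracy stays moderate: the shared penalty keeps unsupported pairs at
the cap weight $1/\epsilon$, and BIC selects a sparse solution.

## Problem sizes used in tests and the acceptance script

The packaged benchmark (`run_benchmark()`) runs the full factorial of the
study (two cases, two sample sizes, four methods). The acceptance script
reproduces the replicate-averaged table quantities at 50 replicates; the
test suite uses 6-10 replicates for the qualitative orderings and
calibration checks, which we found ample for the orderings that are
stable at all, and runs in roughly ten minutes on one CPU. One replicate
of the full four-method comparison takes about 4 s at n = 100 and about
20 s at n = 30 (where the separate conditional fit spends its sweep
budget on degenerate subproblems).

## Known limitations

- The LLA solution is local; pathological initializations can change the
  selected support. The objective path is recorded so this is auditable.
- BIC consistency is not guaranteed for the nonconvex path; under strong
  signals it tends to select somewhat denser models than the noise floor
  requires.
- The eQTL scan is single-marker with per-gene permutation thresholds
  (expression permuted, genotypes fixed); interval mapping and multi-QTL
  models are out of scope.
- The ROC averaging is vertical (by matched grid index across replicates).
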