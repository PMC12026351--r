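---
title: "Information matrices: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information matrices: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infomat)
```

## The object

For a pair of jointly distributed length-`m` sequences $(X^m, Y^m)$, the
information matrix collects the $m^2$ conditional mutual information terms

$$\mathbf{I}_{i,j} \;=\; I\!\left(X_i;\, Y_j \mid X^{i-1},\, Y^{j-1}\right),$$

the dependence between step $i$ of the X-process and step $j$ of the
Y-process given the joint past of both.  The chain rule for mutual
information makes the entries sum to $I(X^m; Y^m)$, and the sequential
measures of interest are subset sums: directed information
$I(X^m \to Y^m)$ is the upper triangle including the diagonal, its
$k$-delayed variant shifts the triangle $k$ positions off the diagonal,
each transfer entropy term $T^{X\to Y}_{i+1}(i,i)$ is a partial column that
never touches the diagonal, and the instantaneous information is the
trace.  Massey's conservation law, the past/present decomposition, and the
transfer-entropy decompositions of delayed directed information are then
*rearrangements of the same addends*: `decomposition_report()` evaluates
every one as a subset sum and reports residuals, which vanish to
floating-point rounding for any matrix whatsoever.  The identity check in
`verify_identities()` uses a relative tolerance of $10^{-9}$ (floored at
magnitude 1): only summation order can make the two sides differ, so
anything larger indicates a bookkeeping bug, not estimation error.

Two conventions are fixed once.  Internally all indexing is 0-based
half-open; every user-facing argument and report uses the 1-based
convention of the transfer-entropy literature, which avoids off-by-one
drift between the triangle, the partial columns and the diagonal.  The log
base (`"e"` for nats, `"2"` for bits) is a property of the estimated
matrix, set at estimation time, and every derived measure inherits it;
continuous-data examples conventionally use nats, channel rates bits.

One delayed-directed-information identity deserves a note: the
transfer-entropy decomposition is checked, for every delay $k$, as the
matrix-level statement that the $k$-shifted triangle equals the sum of its
partial columns.  That subset identity is what the underlying argument
actually uses; for $k > 1$ the partial columns are no longer transfer
entropy terms in the standard parameterization, and the package does not
pretend otherwise.

## Dataset construction

All estimators consume replicated windows: the recording $(x^n, y^n)$ is
split into `N` aligned windows of length `m`, and entry $(i,j)$ sees the
four nested prefix views $(x^{i-1},y^{j-1})$, $(x^i,y^{j-1})$,
$(x^{i-1},y^j)$, $(x^i,y^j)$ per window.  The default split is
**disjoint** (`N = floor(n/m)`), under which windows are independent when
the process is block-i.i.d. and the estimator's bias/variance guarantees
apply.  The **sliding** split (`N = n - m`, every offset) multiplies the
replicate count for short recordings at the cost of dependent replicates —
variance guarantees no longer hold, and the function warns accordingly.
One split is shared by all $m^2$ entries so that entries are comparable;
windows are never re-segmented per entry.

All coordinates are centered with their global mean over the whole
recording before Gaussian estimation (the model assumes zero-mean
variables); per-window centering would bias small-`N` covariances.

When fewer than two windows fit (`m < n < 2m`) the split proceeds with a
single window and warns rather than failing: a one-window "estimate" is
occasionally useful for exploration, but nothing statistical can be said
about it.

## Gaussian estimator

Under joint Gaussianity each entry has the closed form

$$\mathbf{I}_{i,j} \;=\; \tfrac12 \log
\frac{|K_{X^i,Y^{j-1}}|\;|K_{X^{i-1},Y^j}|}
     {|K_{X^{i-1},Y^{j-1}}|\;|K_{X^i,Y^j}|},$$

with the convention $|K_\emptyset| = 1$, so the $(1,1)$ entry reduces to
the unconditional Gaussian mutual information
$-\tfrac12\log(1-\rho^2)$.  The implementation estimates the single
covariance of the stacked window $(X^m, Y^m)$ once; every prefix
covariance is a principal submatrix of it, so all $m^2$ entries derive
from one estimate and $(m+1)^2$ Cholesky factorizations.  This is both
faster and self-consistent — the four covariances entering one entry can
never disagree about a shared block.

Numerical choices:

* log-determinants come from Cholesky factors, never from explicit
  determinants of products, which underflow already for moderate window
  lengths;
* a relative ridge (`ridge`, default $10^{-10}$ times the mean diagonal)
  is added before factorization; a covariance that is singular even after
  ridging raises an error naming the offending prefix;
* negative entry estimates are kept.  Population entries are nonnegative,
  but flooring estimates at zero would destroy the exact conservation
  identities, which are the package's core contract.  Clipping exists only
  as a display option of `render_heatmap()`.

The estimator is exactly invariant under separate invertible *linear* maps
of the two processes, consistent for jointly Gaussian data, and its
variance decays like $1/n$ — the test suite checks the log-variance slope
over $n \in \{10^3, 10^4, 10^5\}$ (30 seeded replicates per size) against
$-1 \pm 0.2$ rather than any asymptotic constant, which the theory does
not pin down at finite $n$.

## Plug-in estimator

For finite alphabets each entry uses the four-entropy decomposition

$$\mathbf{I}_{i,j} = H(X^i,Y^{j-1}) + H(X^{i-1},Y^j)
  - H(X^{i-1},Y^{j-1}) - H(X^i,Y^j),$$

with each term a plug-in entropy $-\sum \hat p \log \hat p$ of the
empirical prefix distribution.  Symbols are canonically re-coded as
integers from the observed alphabet (the alphabet is data-defined, not
declared), prefixes are encoded in mixed radix, and the $(m+1)^2$ prefix
entropies are computed once and shared across entries.  No bias correction
(Miller–Madow or otherwise) is applied: the estimator is deliberately the
*standard* plug-in, and corrections would shift the reported channel
rates.

The support of the joint prefix grows like $|\mathcal X|^i |\mathcal Y|^j$,
so the estimator refuses window lengths with $2m$ above `prefix_cap`
(default 12 symbols) unless the cap is raised explicitly, and warns when
the observed support of the longest prefix exceeds a fifth of the
replicate count — at that point entries are definitely undersampled.  The
channel analyses at $m = 10$, $n = 10^6$ binary symbols raise the cap to
20 knowingly: the $2^{20}$-pattern worst case is tempered by the channels'
short memory, and the undersampling warning is expected and harmless
there, as the acceptance values confirm.

Testing relies on an independent enumeration oracle
(`exact_cmi_bruteforce`): it computes the conditional mutual information
of an explicit finite PMF by marginalizing, conditioning on every joint
history, and summing $p \log$ ratios — a different route than the entropy
combination.  Fed samples whose empirical frequencies match a PMF exactly,
the plug-in estimate must agree with the oracle to $10^{-12}$; fed growing
random samples, it must converge to it.

## Gaussianizing-flow estimator

When the data are far from jointly Gaussian, each variable is first
transported to an approximately Gaussian law.  The transform per
coordinate is a mixture of Gaussian CDFs

$$\tau(x; h) = \sum_{j=1}^{k} w_j(h)\, \Phi\!\left(x;\, \mu_j(h),\,
\sigma^2_j(h)\right),$$

followed by $\Phi^{-1}$.  Its derivative in $x$ is a Gaussian mixture
density — a universal approximator — and the map is strictly increasing
for any valid weights, so it is a diffeomorphism in its argument.
Conditioning (the joint history, plus earlier target coordinates in
autoregressive order) enters through a small fully connected network that
outputs the mixture parameters; weights are normalized with a softmax and
variances kept positive through an exponential, so the CDF-mixture
validity constraints hold by construction.

Training maximizes the exact change-of-variables log-likelihood with a
uniform base density.  Because the base log-density on the unit interval
is zero, that likelihood *is* the conditional mixture log-density of the
data — any additive constant is irrelevant to the argmax — so fitting the
flow and fitting a conditional mixture density model coincide, and the
package implements the latter directly with minibatch Adam and analytic
gradients.  Mixture means are initialized at marginal quantiles so the
starting model already matches the marginal roughly.

For entry $(i,j)$, two flows are fitted — $X_i$ given the history and
$Y_j$ given the history — the samples are mapped, and the Gaussian formula
is applied to the transformed samples.  Whether the original conditioning
block should remain in the covariance (computing $I(X'; Y' \mid Z)$) or be
considered absorbed by the conditioner (computing $I(X'; Y')$) is genuinely
ambiguous; both are implemented, and the default is the conditional form
(`cmi_formula = "conditional"`), which degrades gracefully when the
conditioner undertrains: for jointly Gaussian inputs the extra
conditioning is exact rather than approximate.  The estimate is in
general a *lower* bound of the truth — marginally Gaussian outputs need
not be jointly Gaussian — and the tests check for absence of substantial
overshoot rather than unbiasedness.

Defaults (`maf_config()`): $k = 10$ mixture components, a 2×64 tanh
conditioner, 200 epochs of Adam at learning rate $10^{-3}$ with batches of
256, and a clamp of $10^{-6}$ on the uniform output before $\Phi^{-1}$ so
transformed samples stay finite (at the default clamp the most extreme
transformed value is $\Phi^{-1}(10^{-6}) \approx -4.75$).  These are
conventional small-flow settings, recorded in the returned objects and
freely overridable; no attempt was made to tune them per experiment.
Determinism is guaranteed given (seed, config, data): the full-matrix
estimator derives one seed per entry from `config$seed`.  Training that
produces a non-finite loss aborts with advice to reduce the learning
rate, and `estimate_infomat_neural` flags a diverged entry and continues
rather than discarding the other $m^2 - 1$ fits.

## Simulators

The generators cover the conditions the estimators are validated under:

* **Correlated i.i.d. Gaussian pair** ($Y_t = \rho X_t +
  \sqrt{1-\rho^2} Z_t$): per-step mutual information known in closed form;
  the validation setting uses $\rho = 0.9$, i.e. $0.8304$ nats per step.
* **Cyclic shift and invertible distortion**: within each disjoint
  m-window the Y samples are cyclically shifted by $T$ and both margins
  passed through strictly monotone maps.  Dependence moves to the $T$-th
  off-diagonal (with the wrapped remainder at offset $-(m-T)$) and —
  because conditional mutual information is invariant under per-coordinate
  diffeomorphisms — the per-entry values are unchanged.  A logarithmic
  map is only admitted on positive-support data (it is rejected otherwise
  rather than silently producing NaNs); `cube`, `arcsinh` and `exp` are
  the full-support alternatives used for invariance experiments.
* **Coupled Gaussian AR pair** with memory lengths $\bar k_x, \bar k_y$.
  The printed form of such systems includes lag-0 terms on both sides;
  taken literally that makes each process depend on its own present and
  both presents depend on each other.  The package resolves this by a
  declared generation order: $X_t$ is drawn first, $Y_t$ given $X_t$, so
  lag-0 self terms and lag-0 Y-to-X coupling are structurally excluded and
  instantaneous X-to-Y coupling is the single permitted lag-0 term.
  Stationarity (companion spectral radius < 1 of the reduced joint system)
  is enforced at construction, and simulation discards a burn-in of
  $50\max(\bar k_x,\bar k_y) + 100$ steps — long enough that the retained
  stretch is effectively stationary even at spectral radius near 0.9.  A
  `decay` hook exposes per-time coefficient modulation for time-varying
  experiments without committing to any particular schedule.
* **Ising channel** ($Y_t = X_t$ or $X_{t-1}$, fair coin) and **Trapdoor
  channel** (Z- or S-channel with crossover ½ selected by the state, state
  updated as $S_t = S_{t-1} \oplus X_t \oplus Y_t$), both driven by
  channel-oblivious i.i.d. Bernoulli(½) inputs.  Unstated initial
  conditions are fixed and recorded: the Ising pre-transmission input is an
  independent Bernoulli(½) draw; the Trapdoor initial state is 0.
  Feedback-optimized coding schemes are out of scope — their constructions
  live in the channel-coding literature, not here — so only the oblivious
  rates are reproduced.

On the symmetric banded fixtures: equal couplings of 0.3 on all lags up to
$\bar k \in \{2, 4\}$, a natural first choice, yield a companion spectral
radius above 1 — no stationary process exists and `ar_spec()` rejects the
specification.  The band experiments therefore use symmetric couplings of
0.15 ($\bar k = 2$) and 0.08 ($\bar k = 4$), giving spectral radii of about
0.75 and 0.86: comfortably stationary while keeping the off-diagonal band
well above estimation noise at $n = 10^5$.

What the generators do *not* emulate: real physiological or neural
recordings are nonstationary, oversampled relative to their intrinsic
timescale, and contain artifacts; channels in the wild have unknown memory
structure.  Passing tests on these fixtures demonstrates correctness of
the estimators under their stated assumptions (stationarity, known
alphabet, adequate sample size), not robustness to violations of them.
The directional-flow analysis included in the test suite runs on a
*synthetic* cardiorespiratory surrogate (respiration driving heart rate
through its recent past) and validates the pipeline and the direction
ordering — it is not a substitute for analyzing a real recording, which
users can do by pointing `read_paired_series()` at any delimited export.

## Problem sizes

The validation suite uses $n = 10^5$ samples for closed-form Gaussian
comparisons (entry standard error well under 0.01 nats), $n = 10^6$
symbols with $m = 10$ disjoint blocks for the channel rates, reduced
training budgets (windows of 2–3 steps, $10^4$–$2\times10^4$ samples,
30–150 epochs) for the flow estimator's unit tests with tolerances set
accordingly (0.05 nats), and the full default budget for its single-entry
closed-form check.  The acceptance script re-simulates everything from a
user-supplied seed.

## Known limitations

* The flow estimator trains $m^2$ model pairs; no weight sharing or
  amortization across entries is attempted, so cost grows quadratically in
  the window length.  Use the Gaussian estimator for large `m`.
* The plug-in estimator is vulnerable to undersampling for long prefixes;
  it warns but cannot correct.  Context-tree or other smoothing estimators
  are not implemented.
* Only pairs of processes are supported; higher-order information tensors
  over three or more processes are out of scope.
* Estimated entries are noisy around zero and may be slightly negative;
  all derived measures inherit that noise.  The conservation identities
  hold regardless — they constrain the arithmetic, not the estimation
  error.
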