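---
title: "Block spin Ising models: theory, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block spin Ising models: theory, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockspin)
```

## The model

`blockspin` studies $N$ dependent $\pm 1$-valued variables ("votes",
"traits") partitioned into $M$ latent groups of sizes $N_1,\dots,N_M$, with
group fractions $\alpha_l = N_l/N$. A symmetric positive-definite coupling
matrix $J \in \mathbb{R}^{M\times M}$ sets the interaction strength within
and across groups, and configurations $x \in \{-1,1\}^N$ carry the Gibbs
weight $Z^{-1}e^{-\mathbb{H}(x)}$ with

$$\mathbb{H}(x) = -\frac12 \sum_{l,m} \frac{J_{lm}}{\sqrt{N_l N_m}}
  \, s_l \, s_m, \qquad s_l = \sum_{i\,:\,\iota(i)=l} x_i .$$

The double sum over individuals includes the $i=j$ diagonal terms; they add
a configuration-independent shift that cancels in the probabilities but is
part of the raw energy values the package reports. Positive couplings
reward agreement; negative cross-couplings model antagonistic groups. For
$M=1$ the model is the classical Curie–Weiss ferromagnet with inverse
temperature $J_{11}$, which is why $J$ needs no separate temperature
parameter.

The spectrum of $I-J$ splits the parameter space into three regimes:
*high temperature* ($I-J \succ 0$, weak dependence), *low temperature*
($I-J$ has a negative eigenvalue, strong dependence) and the *critical*
boundary. `spin_regime()` classifies with a spectral tolerance of
$10^{-10}$ times the largest absolute eigenvalue; on the boundary the
package reports `critical` and all detection machinery refuses to run,
since the limiting correlation structure is qualitatively different there
and no windowed clustering applies.

## The free energy and its conventions

All asymptotics flow through the integral representation of the partition
function obtained by a Hubbard–Stratonovich transformation: expectations
become ratios of integrals of $e^{-NF}$ over $\mathbb{R}^M$, with

$$F(x) = \tfrac12 x^\top J^{-1} x
  - \sum_l \alpha_l \ln\cosh\!\big(x_l/\sqrt{\alpha_l}\big).$$

Two conventions deserve emphasis, because renderings of this functional
without the $\sqrt{\alpha_l}$ scalings are common and are *not* consistent
with the Hamiltonian above:

* the $\sqrt{\alpha_l}$ inside $\cosh$ (and inside every $\tanh$ factor
  below) is forced by carrying out the transformation: summing
  $e^{u^\top s(x)}$ over configurations produces
  $\prod_l \cosh^{N_l}(u_l/\sqrt{\alpha_l})$. It is the unique convention
  under which the Hessian of $F$ at the origin equals $H = J^{-1} - I$
  exactly, which `free_energy_derivatives()` asserts in closed form:
  $\mathbf{H}F(x) = J^{-1} - I + \mathrm{diag}\,\tanh^2(x_l/\sqrt{\alpha_l})$.

* the high-temperature pair-correlation limit carries the group sizes. The
  Laplace approximation of the integral ratio around the unique minimum at
  the origin gives, for $i \ne j$ in groups $l, m$,
  $$\mathbb{E}(X_i X_j) \;\longrightarrow\;
    \frac{H^{-1}_{lm}}{\sqrt{N_l N_m}}
    \;=\; \frac{K_{lm}}{N}, \qquad
    K = D_\alpha^{-1/2} H^{-1} D_\alpha^{-1/2},$$
  at rate $(\ln N)^{(6+M)/2}/N^2$. We call $K$ the *size-adjusted limit
  matrix*; it is the inverse of the symmetric positive-definite matrix
  $D_\alpha^{1/2} H D_\alpha^{1/2}$, so the strict bound
  $K_{lm} < \max(K_{ll}, K_{mm})$ for $l \ne m$ — the property the
  detection algorithm rests on — holds for $K$ exactly as it does for
  $H^{-1}$. The package validates this limit (not merely assumes it) by
  comparing it with exact correlations computed through the sufficient
  statistic at $N$ up to several hundred; the discriminating case is a
  two-group model with unequal sizes and diagonal $J$, where the groups are
  independent Curie–Weiss systems and the within-group correlation is
  provably $\beta_l/((1-\beta_l)N_l) = K_{ll}/N$, not $H^{-1}_{ll}/N$.

In the low-temperature non-critical case $F$ has finitely many global
minima $z^{(1)},\dots,z^{(K)}$, in sign-symmetric pairs, each with a
positive-definite Hessian $H_k$. The limiting correlations are the Gram
matrix of the per-group vectors

$$\vec Z_l[k] = \frac{\det(H_k)^{-1/4}\,
  \tanh\!\big(z^{(k)}_l/\sqrt{\alpha_l}\big)}
  {\big(\sum_j \det(H_j)^{-1/2}\big)^{1/2}},$$

so that $\mathbb{E}(X_iX_j) \to \langle \vec Z_{\iota(i)}, \vec
Z_{\iota(j)}\rangle$ at rate $(\ln N)^{(M+3)/2}/N$. The normalisation of
$\vec Z_l$ is the unique one making the Gram matrix equal the leading
Laplace term; `z_vectors()` carries a test-suite cross-check against exact
correlations. For the $M=1$ ferromagnet at $\beta = 2$ this machinery
collapses to the textbook answer: minima at $\pm\beta m^*$ with
$m^* = \tanh(\beta m^*)$, and a limiting correlation of $m^{*2}$.

Detection requires $\vec Z_l \ne \vec Z_m$ for $l \ne m$. This is a real
restriction, not a technicality: a symmetric two-group model with
*positive* cross-coupling has aligned minima, identical $\vec Z$ vectors,
and within- and cross-group correlations converging to the same value — the
groups are asymptotically indistinguishable from pair correlations. The
antagonistic variant (negative cross-coupling) has $\vec Z_1 = -\vec Z_2$
and separates cleanly; the package's low-temperature examples use it, and
`z_vectors()` flags the non-identifiable case so `level_spec()` can refuse.

## Exact sampling

The Gibbs measure depends on $x$ only through the group-sum vector $s$, so
the pushforward onto $s$ — a distribution on $\prod_l (N_l+1)$ points with
weights $\prod_l \binom{N_l}{(N_l+s_l)/2} e^{-\mathbb{H}(s)}$ — is
enumerable whenever that product is below the configurable cap (default
$5\times 10^6$; three equal groups up to $N \approx 500$). `draw_sample()`
draws $s$ from this distribution and then places the $(N_l+s_l)/2$ positive
spins of each group uniformly at random, giving *exact* i.i.d. draws; both
stages consume one explicitly seeded RNG stream in a documented order, and
the caller's RNG state is never touched. Binomial coefficients are computed
in log space via `lchoose` and weights normalised by log-sum-exp, so no
underflow occurs at any feasible size. The same decomposition yields exact
pair correlations (`sufficient_pair_correlations()`) from
$\mathbb{E}(X_iX_j \mid s) = (s_l^2-N_l)/(N_l(N_l-1))$ within and
$s_l s_m/(N_l N_m)$ across groups — the workhorse oracle for every
convergence check in the test suite.

Beyond the cap, `gibbs_draw_sample()` provides single-site heat-bath
sweeps. It is approximate (a Markov chain), is labelled as such in the
sample's metadata, and is never used by any validation; the defaults
(`burn_in = 100` sweeps, `thin = 10`) are deliberately conservative for the
small models it is tested on.

## Locating the minima

`find_minima()` is multi-start quasi-Newton: BFGS with the analytic
gradient from every sign pattern in $\{-1,0,1\}^M$ scaled by
$2\sqrt{\alpha}$, plus 50 uniform random starts in $[-R,R]^M$ with $R =
\|J\|_2 + 1$ (every stationary point satisfies $\|z\| \le \|J\|_2$, since
$z = J(\sqrt{\alpha}\tanh(z/\sqrt\alpha))$ componentwise). Candidates are
polished by damped Newton steps with the analytic Hessian, deduplicated at
radius $10^{-5}$ in the max norm, restricted to values within $10^{-9}$ of
the best, and closed under $z \mapsto -z$ (F is even). Each survivor must
pass a gradient-norm check at $10^{-8}$ and have a positive-definite
Hessian; failure of the latter is reported as a critical landscape rather
than silently accepted. The start grid grows as $3^M$, which is the
intended operating range (the package targets small numbers of groups, not
dozens).

## The detection algorithm

`level_spec()` fixes the regime-specific inputs: the distinct limiting
levels sorted decreasingly — $\mathrm{diag}(K)/N$ in high temperature,
$\|\vec Z_l\|^2$ in low — and the window half-width, $\delta/(4N)$
resp. $\gamma/4$. The separation constants come from
`separation_constants()`:

* high temperature, on a limit matrix $A$:
  $\eta = \min_{l\ne m}\{\max(A_{ll},A_{mm}) - A_{lm}\}$ and
  $\xi = \min\{|A_{ll}-A_{mm}| : A_{ll} \ne A_{mm}\}$, with
  $\delta = \min(\eta,\xi)$;
* low temperature, on the Gram matrix:
  $\eta = \min\{\,\big|\|\vec Z_l\|^2 - \|\vec Z_m\|^2\big| :
  \|\vec Z_l\| \ne \|\vec Z_m\|\,\}$ and
  $\xi = \min\{\,\big|\|\vec Z_l\|^2 - \langle\vec Z_l,\vec
  Z_m\rangle\big| : \|\vec Z_l\| = \|\vec Z_m\|\,\}$, with
  $\gamma = \min(\eta,\xi)$.

A minimum over an empty index set is $+\infty$; when all diagonals are
equal, $\delta = \eta$ and the algorithm still works with a single shared
level (for $M = 1$ both constants are infinite and a single class is
returned trivially). Consecutive levels are separated by at least the
relevant constant, so the closed windows never overlap and each correlation
lies in at most one.

`identify_groups()` then implements the pair recursion literally: at step
$u$, pairs within the window around level $u$ that do not share an index
with any previously claimed pair form the edge set $G_u$; all pairs
touching a claimed individual are excluded from later steps; classes are
the connected components (a small union-find) of $\bigcup_u G_u$. Windows
are closed, so boundary ties are included. Atypical samples — an
individual claimed by no window, a class with edges in two windows, a
within-class pair outside its class's window — yield
`status = "inconsistent_sample"` with per-pair diagnostics instead of an
error, so batch experiments (`recovery_experiment()`) can count failures.
Implementing the recursion on pairs (rather than clustering individuals
directly) mirrors the construction whose correctness is guaranteed on the
typical event, and makes the exclusion bookkeeping auditable in the
diagnostics.

The failure bounds are
$e_{\mathrm{high}}(n) = N^2(n+1)^2\exp\{-\frac18(\delta/(8N))^2 n\}$ and
$e_{\mathrm{low}}(n) = N^2(n+1)^2\exp\{-\frac18(\gamma/8)^2 n\}$, from a
union bound over pairs and a finite-$n$ Sanov-type tail (the quadratic
relative-entropy bound $H(\nu|\theta) \ge \varepsilon^2/8$, available as
`relative_entropy()` / `sanov_upper_bound()` and property-tested, including
the fact that the constant is off by exactly a factor 4 at the fair law).
`min_observations()` inverts the bound beyond its turning point; the result
is a *sufficient* sample size and typically very conservative — in the
package's low-temperature benchmark the bound certifies 80% recovery at
$n^* = 5013$ while the observed rate there is already 100%.

Class labels: classes inherit group names through their level when levels
are distinct; groups sharing a level are matched by size; equal level and
equal size means the model is invariant under exchanging those groups, and
`label_classes()` returns a valid labelling with the affected classes
flagged ambiguous rather than pretending to resolve what no method could.

## Model-free mode

`identify_groups_agnostic()` drops the model: the sorted correlations are
cut into bands at large gaps and the same recursion runs on band centres
and half-ranges. The automatic gap rule splits only when the largest gap
exceeds a quarter of the total correlation range (pure sampling noise has
uniform-ish spacings and never qualifies; planted structure at practical
sample sizes does), then cuts at every gap within a factor 3 of the
largest. This mode is a pragmatic exploration tool — no recovery guarantee
attaches to it, and the test suite exercises it only on clean structure,
constant matrices and pure noise.

## Synthetic data: what the generator does and does not emulate

The generator *is* the model: i.i.d. configurations from the exact Gibbs
measure over a static population with a fixed, known coupling matrix. That
matches the theory's assumptions by construction, so passing tests
demonstrate the correctness of the implementation and the behaviour of the
method *under the model*. Real survey or trait data additionally feature
non-stationary populations, missing responses, item-specific effects and
model misspecification, none of which the generator produces; the agnostic
mode is a first tool for such data precisely because it does not trust the
coupling matrix, but nothing here quantifies robustness to these
departures.

## Numerical choices

* Symmetry of $J$ is enforced at $10^{-12}\max|J|$ and then symmetrised by
  averaging; positive-definiteness at $10^{-10}$ of the largest absolute
  eigenvalue; the same relative tolerance declares regimes critical.
* The de Finetti quadrature (`definetti_pair_correlation()`, the third leg
  of the oracle triangle) truncates to the box where $N(F - \min F) \le
  40$ and uses adaptive `integrate` in one dimension and tensor-product
  Gauss–Legendre with order doubling (64 to 512 nodes per axis, stop at
  $10^{-9}$ stability) in two; generic adaptive 2-D cubature was not
  accurate enough at the $10^{-6}$ cross-validation tolerance, while the
  integrand's analyticity makes Gauss–Legendre converge geometrically.
* Exact-correlation grids used in validation: the oracle triangle runs
  14 models with $M \in \{1,2\}$, $N \in \{4,\dots,12\}$ spanning both
  regimes (sufficient statistic vs. $2^N$ enumeration at $10^{-12}$,
  quadrature at $10^{-6}$); convergence-rate checks use three equal groups
  at $N \in \{30, 60, 120, 240\}$ (high) and $M=1$ at
  $N \in \{50,\dots,400\}$ (low); finite-sample recovery uses $N = 20$,
  $n = 5013$, 50 replicates. These sizes keep every exact computation in
  the enumerable range of the sufficient statistic.

## Known limitations

* **Critical regime**: out of scope throughout; classification is the only
  supported operation there.
* **Near-critical couplings converge slowly.** The Laplace error constants
  blow up as the smallest eigenvalue of $H$ (high) or of the minima's
  Hessians (low) approaches zero. The package's three-party benchmark has
  $\lambda_{\min}(H) \approx 0.13$, and its exact correlations approach
  the $K/N$ levels so slowly that the idealised zero-noise window
  condition $|\mathbb{E}(X_iX_j) - K_{lm}/N| \le \delta/(8N)$ is not yet
  met anywhere in the exactly enumerable range ($N \le 500$;
  extrapolation puts the threshold near $N \approx 10^4$). Detection for
  that model at moderate $N$ therefore needs either the agnostic mode or
  finite-$N$-corrected levels; the asymptotic windows are honest about
  being asymptotic.
* **Label identifiability** is conditional (distinct levels or distinct
  sizes); the symmetric cases are flagged, not resolved.
* **The agnostic mode has no guarantees**, and its gap rule is a heuristic
  tuned to well-separated bands.
* The Gibbs fallback is approximate and deliberately excluded from all
  validation.
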