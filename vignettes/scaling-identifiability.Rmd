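---
title: "Testing structural identifiability by scaling invariance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing structural identifiability by scaling invariance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalesid)
```

## The model class and the question

`scalesid` analyses autonomous ODE models

$$\dot x_i = f_i(x_1,\dots,x_n;\ \lambda_1,\dots,\lambda_m), \qquad
x_i(0) = x_{i,0},$$

in which only a subset of the states is observed. The structural
identifiability question is whether the unobserved degrees of freedom — the
parameters $\lambda_j$, the latent states and any unknown initial
conditions — are pinned down by perfect, continuous observations of the
observed states. The test implemented here looks for one specific and very
common mechanism of non-identifiability: a *scaling symmetry*. If there
exist positive factors $u$ such that

$$\lambda_j \to u_{\lambda_j}\lambda_j,\qquad
x_k \to u_{x_k} x_k \ \ (\text{latent } k),$$

maps solutions to solutions without moving any observed trajectory, then
every parameter with $u_{\lambda_j}\neq 1$ somewhere along that family is
unidentifiable: a whole curve of parameter sets is observationally
indistinguishable.

Observed states are never scaled (we measure them, so their scale is
fixed), and time is never rescaled: a time rescaling would change observed
trajectories whenever they are non-constant, and keeping $t$ fixed matches
the convention of the scaling method this package implements.

## From summands to a linear system

The right-hand sides are first expanded into additive **summands**
(`split_summands()`, `decompose_model()`): for instance
$f = \lambda_1 - \lambda_2 x$ has the summands $\lambda_1$ and
$-\lambda_2 x$. If the summands of one equation are *functionally
independent* — no nontrivial constant linear combination of them vanishes
identically along state space — then invariance of the equation forces
invariance of every summand separately. This is what makes the method
cheap: each summand yields a small, sparse condition of its own.

Independence is certified numerically: each summand is evaluated at
sampled generic points of state space (parameters held at fixed sampled
constants, matching the "functions of time along a trajectory" reading; a
joint-sampling mode exists behind the `joint` flag of
`sampling_config()`), and the set is independent when the value matrix has
full column rank. Summands that fail the test — such as $a x$ and $b x$,
which are proportional along every trajectory — are **merged** and the
merge is recorded in the report: the constraint derived from the merged
summand is the unsplit condition, which is always valid, but additive
redistributions inside the merge (the classic $(a+b)x$ case) are invisible
to any scaling analysis, so merged summands are flagged as scaling-blind.

Writing $u = e^w$ makes the invariance conditions linear. For one summand
$f(\tilde x, \tilde\lambda)$ of the equation of state $i$, invariance of
the finite scaling at first order in $w$ is the identity

$$\sum_{s} a_s \, \Big(s\,\frac{\partial f}{\partial s}\Big)
\;-\; [\,i\ \text{latent}\,]\ a_{x_i}\, f \;\equiv\; 0
\quad\text{in } (x,\lambda),$$

where $s$ runs over the scaled symbols occurring in the summand and the
$-f$ term comes from the scaling of $\dot x_i$ itself. For a monomial
summand this is exactly the finite per-summand matching (the exponents of
the scaling factors add up), and for exponential, rational and
trigonometric summands it is the derivative of the finite condition at
$u=1$ — one uniform piece of linear algebra for every function class.

`generator_condition()` builds the coefficient functions
$c_s = s\,\partial f/\partial s$ symbolically (base R `D()`), and
`assemble_system()` turns the identity into exact rational matrix rows by
collecting it over distinct power-products of symbols and opaque
sub-expressions (exponentials, non-monomial denominators, powers with
symbolic exponents). Initial conditions contribute their own rows: an
unknown-parameter IC ties the state's factor to the IC parameter's factor
($w_{x_i} = w_{x_{i,0}}$), a known nonzero latent IC pins the state
($w_{x_i} = 0$), and a known-zero IC contributes nothing (zero is fixed
by any scaling).

Two details of this symbolic collection deserve a caveat and get one. The
collection treats distinct power-products as linearly independent
functions; that is generically true but can in principle be violated by
special algebraic relations among opaque atoms. For exactly this reason a
second, independent **sampling path** (`method = "sampling"`) builds the
rows by evaluating the coefficient functions at random exact rational
points (numerators and denominators bounded, resampled away from poles),
so the matrix stays exact for rational right-hand sides; summands
containing transcendental functions fall back to double precision rows and
an SVD nullspace there. The package's tests require both paths to produce
identical nullspaces on every catalogue model.

## Solving and classifying

`solve_generators()` computes the exact rational nullspace of the
constraint matrix (fraction-free reduced row echelon form; all arithmetic
is on small exact rationals, so rank needs no tolerance on the symbolic
path). Each basis vector is normalized to a primitive integer vector with
positive leading entry — one **symmetry generator** $a$, meaning
$\lambda_j \to e^{\varepsilon a_j}\lambda_j$ (plus latent-state and
latent-IC scalings) is admissible for every $\varepsilon$.

`render_identifiability_equations()` row-reduces the same matrix and
prints each pivot row as a monomial relation
$\prod_s u_s^{c_s} = 1$ in lowest integer terms — the human-readable
identifiability equations, e.g. for the two-state quadratic example:

```{r}
m <- get_model("twostate_nonlinear")
report <- check_identifiability(m)
report
```

`classify()` applies the verdict rule: a parameter is identifiable, and a
latent state observable, exactly when its coordinate is zero in every
generator. Since the test only detects scaling symmetries, positive
verdicts should be read as "no scaling symmetry found (locally
identifiable by this test)": continuous non-scaling symmetries, discrete
symmetries, and scaling factors constrained to fixed values other than 1
are invisible to the log-linear form, and the report carries a standing
caveat to that effect. A parameter that appears in no equation at all is
reported unidentifiable with an explanatory caveat rather than raising an
error.

**Identifiable groups.** The monomials $\prod_j \lambda_j^{c_j}$ invariant
under all generators form a lattice: integer vectors orthogonal to every
generator, restricted to parameter coordinates. `identifiable_groups()`
returns a primitive integer basis of that lattice with the trivial
single-parameter invariants removed. A basis (rather than the set of all
invariant products) is reported because it is unique up to unimodular
transforms and gives a stable test surface; whether a "group" should be
minimal or maximal is a convention, and this package's convention is the
reduced-row-echelon basis of the orthogonal lattice.

**Initial conditions of observed states** are accepted in all three kinds.
Observedness already pins the state's scaling factor, so a known IC adds
nothing and an unknown-parameter IC simply forces that IC parameter to be
identifiable; the choice is recorded in the report's caveats.

`what_if_observed()` reruns the analysis with latent states moved into the
observed set — the experiment-design question. For the model above,
observing `x2` makes all four parameters identifiable:

```{r}
what_if_observed(m, "x2")$parameters
```

## Numerical cross-validation

The symbolic verdicts are falsifiable numerically, and the package ships
the machinery to do it.

`simulate_with_sensitivities()` integrates the variational system
$\dot S = (\partial f/\partial x)\,S + \partial f/\partial\lambda$
alongside the states (`deSolve::lsoda`, default `rtol = 1e-10`,
`atol = 1e-12`), with one sensitivity column per parameter (zero initial
condition) and per state initial condition (identity initial condition).
`elasticity_matrix()` forms the relative sensitivities
$K_{ij} = (\theta_j/x_i)\,S_{ij}$, stacked over observed states and time
points; entries where $|x_i|$ falls below $10^{-12}\max|x_i|$ are masked,
because the elasticity divides by the state value.

Each generator predicts an exact linear dependence among the columns of
$K$: `dependence_check()` evaluates
$\sum_s a_s K_{\cdot,s}$ row by row (latent-state coordinates act through
the IC columns, scaled by the IC value, so a zero latent IC contributes a
vanishing column) and reports the maximum residual relative to the row
norm. `finite_invariance_check()` applies the finite scaling
$e^{\varepsilon a}$ and integrates base and scaled models; for a true
generator the observed deviation stays at integration noise for any
$\varepsilon$, while injected non-generators produce a deviation that
grows with $|\varepsilon|$ — the package uses both as positive and
negative controls.

Default numerical choices: test points are drawn log-uniformly on
$[1/2, 2]$ (generic positive values away from poles), seed 0 and
configurable everywhere; the SVD rank tolerance for numeric matrices is
$10^{-8}$ relative, matching double-precision integration noise;
`choose_horizon()` doubles the integration horizon (up to 10×) until the
observed states have moved by at least 10% so that elasticities are
informative.

One practical note: models whose observed trajectory is identically zero
(e.g. the two-state example with both ICs zero) satisfy every invariance
check vacuously. The numerical tests therefore use a variant with a
nonzero *observed* initial condition, which leaves the scaling structure
untouched — `x1` is observed, so its IC is never scaled — but makes the
trajectories informative.

## The catalogue and what passing tests show

`catalogue_models()` lists the built-in fixtures. Three entries carry
asserted verdicts and are exercised end-to-end by the test suite: the
death model ($\dot x = -\lambda_1\lambda_2 x$, group $\lambda_1\lambda_2$),
the death-with-immigration model ($\dot x = \lambda_1 - \lambda_2 x$, all
identifiable), and the two-state quadratic model above. The Goodwin
oscillator entry is a reconstructed standard form (Hill feedback with
fixed exponent, known positive ICs, `x1` observed) included as an
unasserted fixture: identifiability verdicts for that family are known to
depend on the exact variant (which ICs are unknown, which states are
measured), so no verdict is asserted for it.

These fixtures are symbolic benchmarks, not data emulators: they exercise
every function class the expression grammar admits and every IC kind, at
desk scale (systems of 1–3 states; the full suite runs in seconds). What
passing tests show is that the constraint construction, the exact linear
algebra and the numerical cross-checks agree with each other and with
closed-form solutions where those exist. What they do not show is
robustness to features of real modelling practice outside the model
class: observation functions $y = g(x,\lambda)$, time-dependent forcing,
events, or noise — all rejected at parse time or out of scope.

## Known limitations

* The test is local and scaling-specific: discrete symmetries and
  non-scaling continuous symmetries are not detected, so "identifiable"
  verdicts are one-sided evidence.
* Translation-type non-identifiability ($(a+b)x$) is structurally
  invisible to scalings; the summand merge records and flags these cases.
* The symbolic collection path assumes distinct power-products of atoms
  are independent; pathological algebraic coincidences would over-constrain
  the system. The rational-sampling path exists as an independent check,
  and a rank-deficient sample could in principle be non-generic — seeds
  and sample sizes are therefore recorded in every certificate.
* Exact rational arithmetic uses integer-valued doubles with an overflow
  guard at $2^{48}$; expressions with very large integer powers switch the
  sampling path to floating point (the symbolic path is unaffected).
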