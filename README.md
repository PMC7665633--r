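# scalesid

Local structural identifiability testing for ODE models by scaling
invariance.

## The problem

A kinetic model `dx_i/dt = f_i(x_1..x_n; λ_1..λ_m)`, of which only a subset
of states is experimentally observed, may be *structurally unidentifiable*:
different parameter sets produce exactly the same observable output, so no
amount of noise-free data can pin the parameters down. Fitting such a model
silently returns arbitrary members of an equivalence class. Modellers in
systems biology, pharmacokinetics and viral dynamics need a cheap test to
run *before* estimating parameters.

`scalesid` implements a scaling-symmetry test. Scale every parameter and
every latent (unobserved) state by an unknown positive factor,

    λ_j → u_{λ_j} λ_j,    x_k → u_{x_k} x_k  (latent k only),

and ask which factors leave all observed trajectories unchanged. Writing
`u = e^w`, invariance of each *functionally independent summand* of each
right-hand side becomes a homogeneous linear system in the log-factors `w`.
Its exact rational nullspace is a basis of one-parameter symmetry families:

* a parameter (or latent state) whose coordinate vanishes in every
  generator has `u = 1` forced — it is **identifiable** (**observable**);
* the remaining coordinates move together along monomial invariants — the
  **identifiable groups** (Buckingham-Π style combinations such as `λ1·λ2`
  in a death model `dx/dt = −λ1λ2x`), estimable even when their factors are
  not.

The symbolic verdict is cross-validated numerically: forward sensitivities
`S_ij = ∂x_i/∂λ_j` are integrated via the variational system, the
elasticity matrix `K_ij = (λ_j/x_i) S_ij` is checked for the exact column
dependence each generator predicts, and the finite scaling
`λ → e^{εa} λ` is applied to verify that observed trajectories are
invariant.

The test is *local*: discrete symmetries and fixed scaling values other
than 1 are outside its reach, and positive verdicts mean "no scaling
symmetry found".

## Worked example

The two-state quadratic model with `x1` observed and zero initial
conditions:

```r
library(scalesid)
m <- ode_model(
  states   = c("x1", "x2"),
  params   = c("lambda1", "lambda2", "lambda3", "lambda4"),
  rhs      = c(x1 = "lambda1*x1^2 + lambda2*x1*x2",
               x2 = "lambda3*x1^2 + lambda4*x1*x2"),
  observed = "x1",
  init     = list(x1 = 0, x2 = 0))
check_identifiability(m)
```

prints

```
Identifiability equations:
  u_lambda1 = 1
  u_lambda2 * u_x2 = 1
  u_lambda3 / u_x2 = 1
  u_lambda4 = 1
1 nontrivial scaling symmetry generator(s) found.
Parameters:
  lambda1      identifiable
  lambda2      unidentifiable
  lambda3      unidentifiable
  lambda4      identifiable
Latent states:
  x2           unobservable
Identifiable groups:
   lambda2 * lambda3
```

Reading: the latent `x2` can be rescaled freely provided `λ2` is divided
and `λ3` multiplied by the same factor, so neither is individually
estimable, but their product is. Observing `x2` removes the freedom:

```r
all(what_if_observed(m, "x2")$parameters == "identifiable")
#> [1] TRUE
```

Models can also be read from YAML documents (`parse_model("model.yaml")`)
or taken from the built-in catalogue (`get_model("death")`,
`catalogue_models()`). A shell wrapper lives at `inst/cli/scalesid.R`:

```sh
Rscript inst/cli/scalesid.R check --catalogue death --elasticity
# exit 0: all parameters identifiable, 3: unidentifiable findings, >=10: error
```

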