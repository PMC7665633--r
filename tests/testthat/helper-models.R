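# Shared fixtures built in code.

death_doc <- function() {
"states: [x]
params: [lambda1, lambda2]
odes:
  x: -lambda1*lambda2*x
observed: [x]
init:
  x: x0
"
}

twostate_doc <- function() {
"states: [x1, x2]
params: [lambda1, lambda2, lambda3, lambda4]
odes:
  x1: lambda1*x1^2 + lambda2*x1*x2
  x2: lambda3*x1^2 + lambda4*x1*x2
observed: [x1]
init:
  x1: 0
  x2: 0
"
}

# two-state model with a nonzero observed initial condition, so trajectories
# are non-trivial for the numerical cross-checks (the scaling structure is
# unchanged: x1 is observed, x2(0) = 0 scales trivially)
twostate_numeric <- function() {
  ode_model(states = c("x1", "x2"),
            params = c("lambda1", "lambda2", "lambda3", "lambda4"),
            rhs = c(x1 = "lambda1*x1^2 + lambda2*x1*x2",
                    x2 = "lambda3*x1^2 + lambda4*x1*x2"),
            observed = "x1",
            init = list(x1 = 1, x2 = 0))
}

# latent state feeding an observed equation through an exponential
exp_latent_model <- function() {
  ode_model(states = c("x1", "x2"),
            params = c("lambda", "mu"),
            rhs = c(x1 = "exp(lambda*x2)", x2 = "-mu*x2"),
            observed = "x1",
            init = list(x1 = 0, x2 = "x20"))
}

generator_from <- function(...) {
  e <- c(...)
  structure(list(exponents = structure(as.integer(e), names = names(e))),
            class = "sid_generator")
}

expo_sorted <- function(g) {
  e <- g$exponents
  e <- e[order(names(e))]
  if (any(e != 0) && e[which(e != 0)[1]] < 0) e <- -e
  e
}

strip_timestamp <- function(js) {
  gsub("\"timestamp\"[^,\n]*", "", js)
}
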