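# One-state death model: the decay rate is a product of two parameters,
# so only the product lambda1*lambda2 is estimable from observations of x.
states: [x]
params: [lambda1, lambda2]
odes:
  x: -lambda1*lambda2*x
observed: [x]
init:
  x: x0
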