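# Worked example: normal-inverse-Wishart mixture prior (unknown
# covariance), only visit 1 observed; the visit-2 marginal is sampled.
prior:
  kind: niw
  weights: [0.5, 0.5]
  components:
    - mean: [5, 5]
      precision_scalar: 20
      scale: [[20, 10], [10, 20]]
      dof: 2
    - mean: [5, 5]
      precision_scalar: 1
      scale: [[20, 10], [10, 20]]
      dof: 2
data:
  xbar: [6]
  cov: [[18]]
  "n": 30
observed: 1
level: 0.95
n_draws: 200000
seed: 1
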