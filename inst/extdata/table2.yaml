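# Worked example: the same two-visit prior, but only visit 1 observed
# (J = 1, K = 1).
prior:
  kind: mvn
  weights: [0.5, 0.5]
  components:
    - mean: [5, 5]
      cov: [[1, 0.5], [0.5, 1]]
    - mean: [5, 5]
      cov: [[20, 10], [10, 20]]
data:
  xbar: [6]
  cov: [[18]]
  "n": 30
observed: 1
level: 0.95
seed: 1
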