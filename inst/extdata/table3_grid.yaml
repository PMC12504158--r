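# Operating-characteristics grid: the three headline cells of the
# open-label-extension simulation study (equipoise prior weights).
reps: 10000
seed: 1
scenarios:
  # null data, intercept-slope model, linear planning prior
  - {trajectory: null_, effect: 0, prior_mean: linear,
     model: intercept_slope, weight: 0.5}
  # null data, by-visit model, linearly declining prior means
  - {trajectory: null_, effect: 0, prior_mean: linear,
     model: by_visit, weight: 0.5}
  # dog-leg data (200 mL effect), by-visit model, dog-leg prior means
  - {trajectory: dog_leg, effect: 200, prior_mean: dog_leg,
     model: by_visit, weight: 0.5}
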