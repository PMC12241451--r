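# Canonical snow-cover-disappearance run: text-derived default parameters
# (d_j and d_e are non-text-derived placeholders; substitute calibrated
# values where available) and the five published winter scenarios.
parameters:
  d_a1: 0.875
  d_a2: 0.875
  d_a3: 0.875
  d_j: 0.85
  d_e: 0.8
  d_w: 0.7
  a: 0.125
  e1: [4.75, 4.75, 4.75, 4.75, 0.0, 0.0]
  e2: [4.75, 4.75, 4.75, 4.75, 0.0, 0.0]
initial_state:
  J: 100
  N1: 100
  N2: 100
  N3: 100
scenarios:
  - name: "0"
    mortality: 0.0
  - name: "1"
    t_min: -5.5
    mortality: 0.03
  - name: "2"
    t_min: -8.0
    mortality: 0.23
  - name: "3"
    t_min: -10.0
    mortality: 0.50
  - name: "4"
    t_min: -14.0
    mortality: 0.95
run:
  n_seasons: 20
  extinction_threshold: 1.0
  bookkeeping: literal
  seed: 1
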