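# Scaled-down "desk" profile: 8 chromosomes / 40 Mb, rod cutoff 1 Mb,
# 1e6 pairs; runs end-to-end on one CPU in minutes.
seed: 1
output_dir: dinochrom_out
simulate:
  n_chromosomes: 8
  total_length: 40.0e6
  depth: 1.0e6
  alpha: -0.4
  d_max: 1.0e6
  beta: 0.5
  tau: 2.0
matrix:
  resolution: 10000
  max_iter: 200
  tol: 1.0e-5
  mad_filter: 5
insulation:
  window: 500000
  resolution: 10000
  delta_span: 100000
  strength_min: 0.2
scaling:
  fit_min: 50000
  fit_max: 500000
pileup:
  flank: 500000
  min_sites: 10
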