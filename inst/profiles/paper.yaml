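# Full-scale analysis profile: parameters for a real dataset
# (insulation window 500 kb at 10-kb bins, strength >= 0.2, P(s) regime-II
# fit over 50 kb - 2 Mb, +/-500-kb pileups). Point `inputs` at your files
# and drop the simulate stage.
seed: 1
output_dir: dinochrom_out
stages: [matrix, insulation, scaling, genes, pileup]
inputs:
  pairs: contacts.pairs
  chromsizes: chrom.sizes
  genes: genes.gff3
matrix:
  resolution: 10000
  max_iter: 400
  tol: 1.0e-5
  mad_filter: 5
insulation:
  window: 500000
  resolution: 10000
  delta_span: 100000
  strength_min: 0.2
scaling:
  fit_min: 50000
  fit_max: 2000000
pileup:
  flank: 500000
  resolution: 10000
  min_sites: 10
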