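# Default frost-trial design: 128 varieties (auto-named V001..V128) x three
# urea-N treatments x two replicates, three nadir photos per plot
# (768 plots, 2304 images). Plot geometry carried as metadata.
n_varieties: 128
treatments:
  - label: N1
    rate: 0
  - label: N2
    rate: 180
  - label: N3
    rate: 240
replicates: 2
images_per_plot: 3
plot_size_m: [1.5, 1.5]
rows_per_plot: 6
row_spacing_cm: 25
replicate_kind: biological and technical
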