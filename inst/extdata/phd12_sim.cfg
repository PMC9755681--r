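# Reference simulation config for the Ph.D.-12 style fixture.
# Paths are relative to this file.
layout = phd12_layout.cfg
sheet = phd12_samples.csv
spectra = phd12_spectra.tsv
wt_rate = 0.05
sub_rate = 0.005
hp_indel_rate = 0.005
qual_mean = 34
qual_slope = -0.02
seed = 1
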