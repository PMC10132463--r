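# Synthetic-neuropil regime presets.
#
# Printed anchors (correlations, density scaling, bouton count, section
# geometry) follow the study conditions; absolute size scales, occupancy
# and morphology mix are synthetic choices documented in the package
# vignette. Areas are in nm^2 on the log scale (log_mean/log_sd of a
# lognormal). rho_sb / rho_mb are target raw-scale Pearson correlations
# of summed synapse area and summed mitochondrion area with bouton
# surface area. density_scale rescales bouton density relative to YA and
# is realized by deepening the stack at fixed bouton count.
common:
  n_boutons: 160
  bouton_log_sd: 0.45
  synapse_log_sd: 0.50
  mito_log_sd: 0.35
  mito_occupancy: 0.45
  occupancy_slope: 0.7
  morph_mix: {straight: 0.80, curved: 0.12, toroidal: 0.08}
  section_thickness_nm: 60
  pixel_nm: 8
  volume_xy_px: [2500, 1375]     # 20 x 11 um at 8 nm
  subthreshold_frac: 0.05
  extra_synapse_rate: 0.15
  extra_mito_rate: 0.20

regimes:
  YA:
    rho_sb: 0.68
    rho_mb: 0.65
    density_scale: 1.0
    n_sections: 41
    bouton_log_mean: 13.7102    # geometric mean 0.90 um^2
    synapse_log_mean: 11.4616   # geometric mean 0.095 um^2
    mito_log_mean: 11.8494      # geometric mean 0.14 um^2
  AU:
    rho_sb: 0.80
    rho_mb: 0.69
    density_scale: 0.72
    n_sections: 57              # 41 / 0.72, deeper stack at fixed count
    bouton_log_mean: 13.9554    # geometric mean 1.15 um^2
    synapse_log_mean: 11.6952   # geometric mean 0.12 um^2
    mito_log_mean: 12.0436      # geometric mean 0.17 um^2
  AI:
    rho_sb: 0.61
    rho_mb: 0.19
    density_scale: 0.72
    n_sections: 57
    bouton_log_mean: 13.9554
    synapse_log_mean: 11.8845   # geometric mean 0.145 um^2 (larger ratio)
    mito_log_mean: 11.9512      # geometric mean 0.155 um^2
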