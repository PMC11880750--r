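# Reference simulation scenario: a 12-model syngeneic panel with paired
# bulk TPM and MVD(IHC), derived from a 14-cluster single-cell dataset.
# Fields mirror panel12_scenario(); read with read_scenario_yaml().
seed: 1
n_genes: 1000
n_clusters: 14
markers_per_cluster: 40
marker_log2fc: 2
baseline_mean: 0.5
cells_per_cluster: 400
dispersion: 2
n_models: 12
ec_fraction_range: [0.02, 0.25]
immune_fraction_range: [0.02, 0.25]
mvd_slope: 1000
mvd_noise_sd: 35
bulk_noise_sd: 0.55
replicates_per_model: 5
alpha: 0.05
lfc_threshold: 1
k: 20
signature_size: 6
specificity_threshold: 0.15
tgep_size: 18
growth_rate: 0.18
days: [1, 3, 5, 7, 9, 11, 13, 15]
n_animals: 8
growth_noise_sd: 0.1
day: 15
effect_map:
  NT: 0
  drugA:
    MVD-high/Tcell_inf_GEP-high: 0.8
    MVD-high/Tcell_inf_GEP-low: 0.8
    MVD-low/Tcell_inf_GEP-high: 0.2
    MVD-low/Tcell_inf_GEP-low: 0.2
  drugB:
    MVD-high/Tcell_inf_GEP-high: 0.6
    MVD-high/Tcell_inf_GEP-low: 0.1
    MVD-low/Tcell_inf_GEP-high: 0.6
    MVD-low/Tcell_inf_GEP-low: 0.1
  combo:
    MVD-high/Tcell_inf_GEP-high: 1.1
    MVD-high/Tcell_inf_GEP-low: 0.9
    MVD-low/Tcell_inf_GEP-high: 1.0
    MVD-low/Tcell_inf_GEP-low: 0.3
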