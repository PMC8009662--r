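# Demo configuration for run_pipeline(): small synthetic field, quick to run.
seed: 1
n_cells: 6
n_traces: 3
n_founders: 200
n_portions: 63
band_width: 3
top_k: 10
detect_contrast: 0.2
detect_snr: 2.0
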