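# Example breathsvm pipeline configuration.
# Omitted fields fall back to the defaults of run_config(): the published
# chamber protocol, VOC footprints, segment scheme and (gamma, C) grid.
seed: 1
out_dir: breathsvm_out
n_per_class: 10
segment: SteadyState
period: 5
mixture: true     # acetone + ethanol footprints; false = acetone only
noise_sd: 0.05
# gamma / C left unset: cmd_train grid-selects them by cross-validation
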