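# Default simulation conditions for the hierarchical ephemeral speciation
# model.  Rates are per incipient lineage per Myr; the incipient branching
# rate sits ~33x above the full-species formation rate, inside the 30-40x
# range reported for subspeciation relative to speciation.
model: ephemeral
lambda_i: 1.0      # incipient speciation (branching) rate
mu_i: 0.5          # incipient loss rate (extinction or reabsorption)
lambda_f: 0.03     # full-species formation (conversion) rate
t_max: 10          # horizon, Myr
max_lineages: 50000
seed: 1
replicates: 100
condition_on_survival: true
output_dir: ephemsim-output
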