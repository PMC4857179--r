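# Time-to-event null study: Weibull(2,2) baseline, log-normal kinship
# frailty at h2 = 0.5 on the log-hazard scale, ~20% uniform censoring.
trait: survival
gamma2: 1
n_families: 40
template: llfs8
n_null: 10
maf_min: 0.05
censoring:
  type: uniform
  rate: 0.2
reps: 150
seed: 1
metrics: [LRT_M, LRT_F]
study: "null"
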