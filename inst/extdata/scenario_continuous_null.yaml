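# Continuous-trait null study at h2 = 0.5 on the reference cohort layout;
# lower reps/n_families for a quick desk run, raise to 582 families and
# 1000 reps for the full study.
trait: gaussian
gamma2: 1
sigma2: 1
n_families: 120
template: llfs8
n_null: 10
maf_min: 0.05
reps: 100
seed: 1
metrics: [BIC_M, BIC_J, BIC_Y, BIC_C, AIC_M, LRT_M, BIC_F, AIC_F, LRT_F]
study: "null"
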