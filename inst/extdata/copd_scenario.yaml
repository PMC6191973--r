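# Planning scenario: bronchodilator trial (indacaterol vs tiotropium) in
# chronic obstructive pulmonary disease, outcome 24h postdose FEV1.
# Budget counts subjects; plausible ICC ranges reflect vague prior knowledge.
name: copd_bronchodilator
c_A: 0
c_B: 0
c_t: 0
c_sp: 1
c_s2p: 1
c_ts: 0
rhoA_low: 0.10
rhoA_high: 0.70
rhoB_low: 0.30
rhoB_high: 0.90
ES: 0.5
alpha: 0.05
power: 0.80
effect: treatment
designs: [crossover, extended_parallel, parallel]
sigma_y_sq: 2
n_sim: 0
seed: 1
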