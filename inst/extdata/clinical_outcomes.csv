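metric,baseline_mean,baseline_sd,week4_mean,week4_sd
assist_torque_pct,62,11,45,8
vr_difficulty,0.42,0.09,0.69,0.10
success_rate_pct,61.3,9.2,82.1,6.8
fma_ue,34.2,9.1,43.3,9.0
arat,22.8,8.1,30.4,8.3
grip_kg,11.4,5.8,15.5,6.2
romn,0.62,0.18,0.76,0.15
sparc,1.92,0.31,1.76,0.28
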