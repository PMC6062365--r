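combo,ccr,ccr_sd,sensitivity,sensitivity_sd,selectivity,selectivity_sd
chemical,0.78,0.05,0.72,0.11,0.84,0.06
target,0.67,0.06,0.56,0.12,0.78,0.06
cytotox,0.67,0.06,0.40,0.10,0.93,0.03
chemical+target,0.79,0.05,0.74,0.10,0.84,0.06
chemical+cytotox,0.80,0.06,0.74,0.12,0.86,0.05
target+cytotox,0.73,0.06,0.63,0.13,0.84,0.06
chemical+target+cytotox,0.82,0.05,0.77,0.10,0.86,0.05
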