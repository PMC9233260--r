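model,sens_pct,spec_pct,ppv_pct,npv_pct,acc_pct,youden
A,54.7,82.1,56.8,80.9,73.9,0.368
B,53.0,86.7,67.0,81.6,76.6,0.397
C,54.0,87.3,67.8,82.1,77.3,0.413
PAMT,68.0,78.0,60.6,85.8,75.0,0.460
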