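clone,Bmax1,ka1,kd1,KD1_reported,Bmax2,ka2,kd2,KD2_reported
12F1-1,310.13,2.08e12,6.34e-14,3.05e-16,82.69,1.10e3,1.45e-2,1.32e-5
11B12-1,167.60,2.12e2,3.08e-14,1.45e-16,23.38,3.47e4,3.22e-4,9.27e-9
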