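model,data_augment,se_blocks,pa,cpa_background,cpa_aperture,mpa,miou
A,no,no,0.9633,0.9982,0.6182,0.8082,0.4962
B,yes,no,0.9789,0.9977,0.6628,0.8302,0.5512
C,no,yes,0.9634,0.9982,0.5392,0.7687,0.5074
D,yes,yes,0.9791,0.9978,0.6632,0.8305,0.5590
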