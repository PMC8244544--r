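metric,effect,condition,delta_pct,minuend,subtrahend
miou,data_augment,without_se,5.5,B,A
miou,data_augment,with_se,5.2,D,C
miou,se_blocks,without_augment,1.1,C,A
miou,se_blocks,with_augment,0.8,D,B
mpa,data_augment,without_se,2.2,B,A
mpa,data_augment,with_se,6.2,D,C
mpa,se_blocks,with_augment,0.03,D,B
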