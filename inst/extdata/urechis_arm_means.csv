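cell_id,chromosome_label,short_arm_um,long_arm_um
pair_means,1,1.97,2.20
pair_means,2,1.82,2.15
pair_means,3,2.45,3.48
pair_means,4,1.42,2.21
pair_means,5,1.43,2.40
pair_means,6,1.42,2.94
pair_means,7,1.24,2.94
pair_means,8,1.29,3.29
pair_means,9,0.92,3.08
pair_means,10,0.59,2.59
pair_means,11,0.53,3.29
pair_means,12,0,3.74
pair_means,13,0,3.95
pair_means,14,0,3.09
pair_means,15,0,2.36
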