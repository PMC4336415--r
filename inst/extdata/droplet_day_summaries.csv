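day,mean_diameter_um,sd_diameter_um,n_droplets,conc_mean_cp_per_ul,conc_sd_cp_per_ul,n_replicates
1,117.02,1.37,588,9310,196,8
2,116.59,2.21,605,9586,224,8
3,116.60,3.18,601,9465,352,8
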