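sample,C_O,C_G,C_V,ref_Cp_G,ref_Cp_V,ref_X_ext
Sample 1,1.66,4.55,7.02,2.89,5.36,0.7595
Sample 2,3.16,5.2,6.03,2.04,2.87,0.8405
Sample 3,3.16,5.2,7.37,2.04,4.21,0.8543
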