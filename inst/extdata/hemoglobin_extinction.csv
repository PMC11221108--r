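wavelength_nm,species,molar_extinction_cm1_M1,factor_cm1_uM1
690,O2Hb,276.0,0.0006355134857
690,HHb,2051.96,0.004724812507
830,O2Hb,974.0,0.002242717881
830,HHb,693.04,0.001595783573
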