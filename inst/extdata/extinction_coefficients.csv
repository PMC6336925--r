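wavelength_nm,eps_hbo2,eps_hbr
690,276.0,2051.96
705,350.0,1652.0
730,390.0,1102.2
750,586.0,1405.24
780,710.0,1075.0
808,816.0,723.0
830,974.0,693.04
850,1058.0,691.32
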