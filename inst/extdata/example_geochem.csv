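day,bottle,replicate,sulfate_mM,methane_mM,hydrogen_nM,d13c_ch4_permil,cells_per_ml
0,B1,1,10.9,0.05,0.49,-34.6,2.1e8
0,B2,2,11.2,0.05,0.52,-35.1,1.9e8
0,B3,3,10.8,0.04,0.47,-34.8,2.2e8
30,B1,1,9.3,0.05,0.11,-33.9,3.0e8
30,B2,2,9.5,0.06,0.10,-34.4,2.8e8
30,B3,3,9.2,0.05,0.12,-34.0,3.2e8
60,B1,1,7.9,1.70,0.10,-34.2,4.1e8
60,B2,2,8.1,1.76,0.09,-34.7,3.9e8
60,B3,3,7.8,1.68,0.11,-34.1,4.0e8
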