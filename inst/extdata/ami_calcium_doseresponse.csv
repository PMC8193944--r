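concentration_um,inhibition_pct,sem_pct,n_cells
3,1.87,0.65,5
10,16.02,6.37,8
30,30.25,3.42,7
100,46.29,6.31,6
300,99.26,0.74,3
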