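measure,age,genotype,mean,sem,n
daily_activity,young,WT,14695,2387,6
daily_activity,young,VGAT,15410,1740,6
daily_activity,aged,WT,5358,1744,10
daily_activity,aged,VGAT,1655,382.7,10
phase_angle,young,WT,-7.70,2.63,6
phase_angle,young,VGAT,-4.97,0.97,6
phase_angle,aged,WT,-28.76,3.94,10
phase_angle,aged,VGAT,-30.93,3.57,10
onset_variability,young,WT,18.38,5.03,6
onset_variability,young,VGAT,24.33,5.84,6
onset_variability,aged,WT,54.88,5.70,10
onset_variability,aged,VGAT,61.21,6.49,10
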