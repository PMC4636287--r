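group,cell_type,units,i_basal,i_evoked,i_total,i_bg,i_basal_no_gbg,k_out,holding
low,oocyte,uA,0.73,1.19,1.92,3.49,1.06,24,-80
intermediate,oocyte,uA,3.9,2.3,6.2,12.34,3.77,24,-80
high,oocyte,uA,13.36,3.84,17.2,27.6,15,24,-80
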