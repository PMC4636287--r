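group,cell_type,units,i_basal,i_evoked,i_total,k_out,holding
0.5-3,neuron,pA_pF,1.8,13.5,15.3,25,-70
0.5-3,oocyte,pA_pF,1.82,4.2,6.0,24,-80
0.5-3,hek,pA_pF,1.51,10.5,12.03,24,-80
3-13,neuron,pA_pF,5.8,19.9,25.7,25,-70
3-13,oocyte,pA_pF,7.2,10,17,24,-80
3-13,hek,pA_pF,6.4,16,22.8,24,-80
13-50,neuron,pA_pF,17.3,26.1,43.4,25,-70
13-50,oocyte,pA_pF,28,15.6,43.6,24,-80
13-50,hek,pA_pF,25.7,34,60,24,-80
>50,oocyte,pA_pF,65.9,84.5,84.5,24,-80
>50,hek,pA_pF,67.6,96,164,24,-80
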