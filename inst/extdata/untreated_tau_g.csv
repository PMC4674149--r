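mouse_id,tumor_id,tau_g_days
CM.37,1,6.650
CM.37,2,8.256
CM.37,3,9.868
CM.38,1,9.646
CM.38,2,13.371
CM.38,3,13.381
CM.53,1,37.922
CM.53,2,24.312
CM.53,3,23.510
CM.60,1,12.328
CM.60,2,8.450
CM.60,3,6.809
CM.76,1,27.251
CM.76,2,55.120
CM.76,3,19.439
CM.77,1,30.453
CM.77,2,21.792
CM.77,3,22.155
CM.78,1,13.865
CM.78,2,9.475
CM.78,3,11.645
CM.79,1,45.192
CM.79,2,8.149
CM.79,3,6.244
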