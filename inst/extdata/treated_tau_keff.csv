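mouse_id,tumor_id,tau_g_days,k_eff_ml_per_day_ng,arm
CM.41,1,7.373,5.02e-05,5FU-50
CM.41,2,6.574,7.52e-05,5FU-50
CM.41,3,3.704,1.16e-04,5FU-50
CM.42,1,13.531,5.51e-05,5FU-50
CM.42,2,5.012,7.19e-05,5FU-50
CM.42,3,4.664,5.37e-05,5FU-50
CM.43,1,15.726,2.29e-05,5FU-100
CM.43,2,5.911,4.59e-05,5FU-100
CM.43,3,10.613,2.32e-05,5FU-100
CM.49,1,16.540,2.07e-05,5FU-100
CM.49,2,60.396,2.40e-05,5FU-100
CM.49,3,18.766,1.05e-05,5FU-100
CM.54,1,22.832,1.00e-15,5FU-50
CM.54,2,11.206,3.95e-04,5FU-50
CM.54,3,13.679,2.29e-06,5FU-50
CM.55,1,9.639,3.36e-05,5FU-50
CM.55,2,5.683,7.87e-05,5FU-50
CM.55,3,4.349,9.12e-05,5FU-50
CM.56,1,11.252,1.25e-05,5FU-100
CM.57,1,23.716,2.54e-06,5FU-100
CM.57,2,9.045,2.33e-05,5FU-100
CM.57,3,5.192,4.99e-05,5FU-100
CM.62,1,8.920,2.43e-20,5FU-50
CM.62,2,12.109,1.72e-20,5FU-50
CM.62,3,87.771,3.62e-22,5FU-50
CM.63,2,8.993,2.30e-05,5FU-100
CM.66,1,3.136,1.27e-04,5FU-50
CM.66,2,5.844,7.04e-05,5FU-50
CM.67,1,7.851,2.69e-05,5FU-100
CM.67,2,12.429,1.36e-05,5FU-100
CM.73,1,11.134,8.24e-06,5FU-100
CM.73,2,3.672,4.75e-05,5FU-100
CM.73,3,4.734,4.83e-05,5FU-100
CM.84,1,20.589,1.47e-05,5FU-100
CM.84,2,13.684,1.23e-05,5FU-100
CM.84,3,13.352,6.43e-06,5FU-100
CM.90,1,6.288,9.47e-05,5FU-50
CM.91,1,4.792,5.89e-05,5FU-100
CM.91,2,13.441,1.07e-05,5FU-100
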