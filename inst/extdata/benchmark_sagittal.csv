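metric,device,mean,sd,ccc,ccc_band,cv,loa_upper,loa_lower
cadence,VIC,104.312,5.009,0.996,almost complete,4.802,0.08,-0.93
cadence,OV,104.250,4.969,,,4.766,,
gait_symmetry,VIC,97.000,2.784,0.527,moderate,2.870,4.21,-6.21
gait_symmetry,OV,96.000,2.716,,,2.829,,
gait_variability,VIC,3.031,1.531,0.624,strong,50.494,3.09,-1.34
gait_variability,OV,3.906,1.487,,,38.057,,
step_time,VIC,0.576,0.029,0.974,almost complete,5.036,0.01,-0.01
step_time,OV,0.576,0.029,,,4.980,,
stance_time,VIC,0.723,0.038,0.947,almost complete,5.293,0.03,-0.02
stance_time,OV,0.724,0.040,,,5.512,,
step_length,VIC,62.188,3.292,0.892,almost complete,5.294,3.54,-1.79
step_length,OV,63.062,3.473,,,5.507,,
double_support,VIC,0.293,0.024,0.734,strong,8.198,0.04,-0.03
double_support,OV,0.296,0.023,,,7.677,,
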