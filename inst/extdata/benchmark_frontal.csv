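metric,device,mean,sd,ccc,ccc_band,cv,loa_upper,loa_lower
step_width,VIC,10.625,2.666,0.805,strong/almost complete,25.095,1.26,-3.26
step_width,OV,9.625,1.833,,,19.043,,
step_time,VIC,0.576,0.029,0.975,almost complete,4.951,0.01,-0.01
step_time,OV,0.577,0.028,,,4.777,,
stance_time,VIC,0.723,0.038,0.936,almost complete,5.274,0.03,-0.02
stance_time,OV,0.728,0.050,,,6.850,,
cadence,VIC,104.312,5.009,0.993,almost complete,4.802,1.38,-0.88
cadence,OV,104.562,5.025,,,4.805,,
gait_symmetry,VIC,97.000,2.784,0.108,weak,2.870,4.57,-1.95
gait_symmetry,OV,99.875,0.484,,,0.485,,
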