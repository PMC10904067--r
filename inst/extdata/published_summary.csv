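setting,strategy,reference,cost_per_person,qalys_per_person,incr_cost,incr_qaly,incr_qaly_lo,incr_qaly_hi,icur,icur_lo,icur_hi
rural,none,NA,214.07,12.10231,NA,NA,NA,NA,NA,NA,NA
rural,community,none,228.36,12.10573,14.29,0.00342,0.00145,0.00596,4178.51,3859.33,5342.96
rural,telemedicine,none,235.30,12.11145,21.23,0.00914,0.00782,0.01024,2323.04,1023.16,3902.51
rural,telemedicine,community,235.30,12.11145,6.93,0.00572,0.00407,0.00715,1211.93,896.07,1590.31
urban,none,NA,220.78,12.18423,NA,NA,NA,NA,NA,NA,NA
urban,community,none,238.59,12.18890,17.81,0.00467,0.00309,0.00582,3812.91,2905.72,4167.39
urban,telemedicine,none,244.25,12.19386,23.47,0.00963,0.00780,0.01174,2437.28,1241.60,3519.85
urban,telemedicine,community,244.25,12.19386,5.66,0.00496,0.00326,0.00657,1141.13,859.03,1402.85
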