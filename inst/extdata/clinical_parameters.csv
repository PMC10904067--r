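parameter,setting,group,base,lo95,hi95,family
prevalence_npdr,rural,prevalence,0.256,0.181,0.348,beta
prevalence_pdr,rural,prevalence,0.016,0.003,0.071,beta
prevalence_dme,rural,prevalence,0.035,0.032,0.039,beta
prevalence_npdr,urban,prevalence,0.149,0.106,0.204,beta
prevalence_pdr,urban,prevalence,0.011,0.005,0.023,beta
prevalence_dme,urban,prevalence,0.026,0.023,0.029,beta
normal_to_npdr,both,transition,0.0328,0.0184,0.0578,beta
normal_to_pdr,both,transition,0.0024,0.0009,0.0063,beta
npdr_to_pdr,both,transition,0.0106,0.0040,0.0278,beta
npdr_to_dme,both,transition,0.0107,0.0096,0.0118,beta
pdr_to_dme,both,transition,0.0290,0.0261,0.0319,beta
pdr_to_svi,both,transition,0.0278,0.0100,0.0744,beta
dme_to_svi,both,transition,0.0500,0.0450,0.0550,beta
treated_pdr_to_svi,both,transition,0.0116,0.0005,0.0268,beta
treated_dme_to_svi,both,transition,0.0300,0.0270,0.0330,beta
utility_no_dr,both,utility,0.95,0.92,0.99,beta
utility_npdr,both,utility,0.79,0.71,0.87,beta
utility_pdr,both,utility,0.70,0.63,0.77,beta
utility_dme,both,utility,0.70,0.63,0.77,beta
utility_svi,both,utility,0.55,0.50,0.61,beta
community_normal_called_npdr,both,test,0.05,0.04,0.06,beta
community_normal_called_normal,both,test,0.95,0.86,1.00,beta
community_npdr_called_normal,both,test,0.22,0.20,0.24,beta
community_pdr_called_npdr,both,test,0.03,0.02,0.04,beta
community_pdr_called_normal,both,test,0.02,0.01,0.03,beta
community_dme_sensitivity,both,test,0.82,0.74,0.90,beta
community_dme_specificity,both,test,0.79,0.71,0.87,beta
telemedicine_normal_called_npdr,both,test,0.04,0.03,0.05,beta
telemedicine_normal_called_normal,both,test,0.96,0.86,1.00,beta
telemedicine_npdr_called_normal,both,test,0.42,0.38,0.46,beta
telemedicine_pdr_called_npdr,both,test,0.19,0.17,0.21,beta
telemedicine_pdr_called_normal,both,test,0.02,0.01,0.03,beta
telemedicine_dme_sensitivity,both,test,0.80,0.72,0.88,beta
telemedicine_dme_specificity,both,test,0.95,0.86,1.00,beta
rr_diabetes,both,mortality,1.97,NA,NA,fixed
rr_svi,both,mortality,3.9,NA,NA,fixed
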