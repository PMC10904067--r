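programme,item,kind,units,unit_cost_usd,annual_cost_usd,life_years
community,Nonmydriatic retinal camera,capital,1,24000,5321.51,5
community,Visual acuity chart,capital,1,250,55.43,5
community,Laptop,capital,1,500,110.86,5
community,Medical staff,recurring,6,6500,39000,NA
community,"Posters, leaflets and loose expenses",recurring,NA,NA,700,NA
community,Casual supporting personnel,recurring,NA,NA,640,NA
community,Transportation,recurring,NA,NA,3000,NA
telemedicine,Computer software and peripherals,capital,1,9000,1995.57,5
telemedicine,Installation,capital,1,5000,1108.65,5
telemedicine,Contract cost to other organizations,recurring,1,1700,1700,NA
telemedicine,"Medical staff, specialists",recurring,10,2500,25000,NA
telemedicine,"Medical staff, technicians",recurring,2,2500,5000,NA
telemedicine,Maintenance,recurring,1,2000,2000,NA
hospital,Medical service,exam,NA,NA,8.48,NA
hospital,Fundus photography,exam,NA,NA,4.74,NA
hospital,Optical coherence tomography,exam,NA,NA,13.85,NA
hospital,Visual acuity and noncontact IOP measurement,exam,NA,NA,0.78,NA
hospital,Transportation and accommodation,exam,NA,NA,63.76,NA
hospital,Internal medical examination,exam,NA,NA,8.39,NA
hospital,Photocoagulation,treatment,NA,NA,137.60,NA
hospital,Anti-VEGF therapy,treatment,NA,NA,1741.46,NA
hospital,Follow-up observation (annual),treatment,NA,NA,122.32,NA
hospital,SVI first year,treatment,NA,NA,8800,NA
hospital,SVI subsequent year,treatment,NA,NA,3600,NA
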