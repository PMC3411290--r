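disease,age_at_diagnosis,sex,corrected,fraction_rad_deaths,life_expectancy_years,dle_radiation_days,dle_disease_days,dle_total_days,survival_horizon_pct
HD,0,male,no,0.005,76,29,NA,29,99
HD,0,female,no,0.010,82,64,NA,64,99
HD,0,male,yes,0.003,60,19,5841,5859,93
HD,0,female,yes,0.007,64,41,6560,6601,94
HD,1,male,no,0.006,76,30,NA,30,100
HD,1,female,no,0.011,81,68,NA,68,100
HD,1,male,yes,0.004,60,20,5731,5750,94
HD,1,female,yes,0.007,63,43,6440,6483,94
HD,5,male,no,0.006,72,32,NA,32,100
HD,5,female,no,0.011,77,71,NA,71,100
HD,5,male,yes,0.004,58,21,5205,5226,94
HD,5,female,yes,0.007,61,46,5881,5928,94
HD,10,male,no,0.006,67,32,NA,32,100
HD,10,female,no,0.011,72,68,NA,68,100
HD,10,male,yes,0.004,54,22,4577,4598,94
HD,10,female,yes,0.007,58,46,5213,5259,94
HD,15,male,no,0.007,62,35,NA,35,99
HD,15,female,no,0.012,67,74,NA,74,100
HD,15,male,yes,0.005,51,25,3985,4009,93
HD,15,female,yes,0.008,55,51,4578,4629,94
DLBCL,55,male,no,0.004,25,14,NA,14,96
DLBCL,55,female,no,0.005,29,23,NA,23,98
DLBCL,55,male,yes,0.001,9,2,5931,5933,58
DLBCL,55,female,yes,0.001,9,2,7228,7230,59
DLBCL,65,male,no,0.003,17,9,NA,9,90
DLBCL,65,female,no,0.004,20,13,NA,13,95
DLBCL,65,male,yes,0.001,7,2,3486,3488,55
DLBCL,65,female,yes,0.001,8,2,4354,4356,58
DLBCL,75,male,no,0.002,10,4,NA,4,76
DLBCL,75,female,no,0.002,12,5,NA,5,86
DLBCL,75,male,yes,0.001,6,1,1715,1716,46
DLBCL,75,female,yes,0.001,6,1,2057,2058,52
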