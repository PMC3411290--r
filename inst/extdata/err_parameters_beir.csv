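site,dose_organ,beta_male,beta_female,gamma,eta,theta,delta,phi
stomach,stomach,0.21,0.48,-0.30,-1.4,NA,NA,NA
colon,colon,0.63,0.43,-0.30,-1.4,NA,NA,NA
liver,liver,0.32,0.32,-0.30,-1.4,NA,NA,NA
lung,lung,0.32,1.40,-0.30,-1.4,NA,NA,NA
breast,breast,NA,0.51,0.00,-2.0,NA,NA,NA
prostate,prostate,0.12,NA,-0.30,-1.4,NA,NA,NA
uterus,uterus,NA,0.055,-0.30,-1.4,NA,NA,NA
ovary,ovary,NA,0.38,-0.30,-1.4,NA,NA,NA
bladder,bladder,0.50,1.65,-0.30,-1.4,NA,NA,NA
other_solid,other_solid,0.27,0.45,-0.30,-2.8,NA,NA,NA
thyroid,thyroid,0.53,1.05,-0.83,0.0,NA,NA,NA
leukemia,bone_marrow,1.1,1.2,-0.40,NA,0.87,-0.48,0.42
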