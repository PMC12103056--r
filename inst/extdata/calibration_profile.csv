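measure,group,median,iqr,family,lo,hi,factor,loading
age,MCI,65,5,count,60,72,none,0
age,control,64,5,count,60,72,none,0
education,MCI,15,5,count,10,20,none,0
education,control,15,3,count,10,20,none,0
moca,MCI,22,3,truncnorm,19,25,F1,-0.85
moca,control,27,2,truncnorm,26,30,F1,-0.85
pta_right,MCI,28.3,10.8,truncnorm,5,40,F3,0.9
pta_right,control,26.7,6.67,truncnorm,5,40,F3,0.9
pta_left,MCI,31.7,10,truncnorm,5,40,F3,0.9
pta_left,control,26.7,8.33,truncnorm,5,40,F3,0.9
pta_speech_right,MCI,30,10.6,truncnorm,5,40,F3,0.9
pta_speech_right,control,27.5,6.25,truncnorm,5,40,F3,0.9
pta_speech_left,MCI,32.5,9.38,truncnorm,5,40,F3,0.9
pta_speech_left,control,28.8,8.13,truncnorm,5,40,F3,0.9
dcs,MCI,2,3,count,0,20,F2,0.75
dcs,control,10,4,count,0,20,F2,0.75
total_r,MCI,12,6,count,0,20,F2,0.7
total_r,control,11,2,count,0,20,F2,0.7
total_l,MCI,4,3,count,0,20,F2,0.75
total_l,control,12,2.75,count,0,20,F2,0.75
forced_rcs,MCI,10,6,count,0,20,F2,0.7
forced_rcs,control,13,0.75,count,0,20,F2,0.7
forced_lcs,MCI,7,6,count,0,20,F2,0.75
forced_lcs,control,13,0,count,0,20,F2,0.75
quicksin,MCI,5.5,2,lognormal,NA,NA,F2,-0.3
quicksin,control,5.5,1,lognormal,NA,NA,F2,-0.3
fmdl,MCI,6.84,8.05,lognormal,NA,NA,F1,0.8
fmdl,control,3.65,3.83,lognormal,NA,NA,F1,0.8
mdt,MCI,-6.94,3.01,normal,NA,NA,F1,0.8
mdt,control,-9.82,1.94,normal,NA,NA,F1,0.8
attr,MCI,13,6.64,lognormal,NA,NA,F1,0.8
attr,control,4.9,5.38,lognormal,NA,NA,F1,0.8
tfs_af,MCI,225,5.6,lognormal,NA,NA,F1,-0.8
tfs_af,control,366,214,lognormal,NA,NA,F1,-0.8
dsf_rt,MCI,6490,640,lognormal,NA,NA,F1,0.85
dsf_rt,control,4935,559,lognormal,NA,NA,F1,0.85
dsb_rt,MCI,7686,3215,lognormal,NA,NA,F1,0.85
dsb_rt,control,4221,783,lognormal,NA,NA,F1,0.85
dsf_len,MCI,4,1,span,2,8,F1,-0.8
dsf_len,control,6,1,span,2,8,F1,-0.8
dsb_len,MCI,3.33,1,span,2,8,F1,-0.8
dsb_len,control,5,1,span,2,8,F1,-0.8
tmt_number,MCI,92672,14553,lognormal,NA,NA,F1,0.85
tmt_number,control,70018,8556,lognormal,NA,NA,F1,0.85
tmt_mixed,MCI,305414,67792,lognormal,NA,NA,F1,0.85
tmt_mixed,control,165174,58772,lognormal,NA,NA,F1,0.85
mrt_mirror_acc,MCI,68.5,6.51,percent,0,100,F1,-0.7
mrt_mirror_acc,control,79.2,7.77,percent,0,100,F1,-0.7
mrt_nonmirror_acc,MCI,89.4,2.02,percent,0,100,F2,-0.45
mrt_nonmirror_acc,control,86.9,6.81,percent,0,100,F2,-0.45
mrt_mirror_rt,MCI,2861,337,lognormal,NA,NA,F1,0.8
mrt_mirror_rt,control,1592,381,lognormal,NA,NA,F1,0.8
mrt_nonmirror_rt,MCI,1827,188,lognormal,NA,NA,F1,0.75
mrt_nonmirror_rt,control,1252,358,lognormal,NA,NA,F1,0.75
alerting,MCI,0.0242,0.0489,normal,NA,NA,F2,-0.55
alerting,control,-0.0723,0.0954,normal,NA,NA,F2,-0.55
orienting,MCI,0.0656,0.0232,normal,NA,NA,F2,-0.6
orienting,control,-0.0758,0.102,normal,NA,NA,F2,-0.6
conflict,MCI,0.194,0.0395,normal,NA,NA,F2,-0.55
conflict,control,-0.0157,0.167,normal,NA,NA,F2,-0.55
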