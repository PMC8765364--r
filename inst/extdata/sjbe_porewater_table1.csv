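site_id,season,salinity_psu,po4_um,po4_se,nh4_um,nh4_se,din_um,din_se,ph,np_printed
MPW,wet,16.0,1.7,0.5,24.5,4.9,24.8,4.9,7.1,14.6
MPW,dry,9.7,3.8,0.4,36.2,9.0,42.0,9.8,NA,11.1
MPE,wet,24.7,49.8,8.4,20.8,1.9,23.1,1.9,8.2,0.5
MPE,dry,20.4,93.4,14.5,125.8,31.4,126.8,31.8,NA,1.4
SJ,wet,15.0,4.2,2.6,34.6,13.0,35.0,13.1,7.9,10
SJ,dry,17.6,4.7,2.3,27.8,5.6,29.2,5.4,NA,6.2
Torr,wet,22.7,8.3,2.5,24.9,3.6,26.1,3.5,7.6,3.1
Torr,dry,27.5,9.1,1.8,22.5,2.6,23.1,2.5,NA,2.5
Pin,wet,67.2,3.9,0.6,1057.3,209.1,1057.3,209.1,4.7,271.1
Pin,dry,72.6,31.6,5.5,451.0,76.3,451.3,76.2,NA,14.3
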