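unit,population,buffer_radius_m
watershed,769000,NA
MPW,3953,500
MPE,4303,500
SJ,1729,500
Torr,517,500
Pin,36,500
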