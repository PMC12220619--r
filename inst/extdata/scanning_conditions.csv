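species,preservation_days,preservation_months,rh_percent,temp_c
Oc. abserratus,131,4.3,32.9,22.0
Oc. canadensis,143,4.7,34.2,21.9
Ae. cinereus,170,5.6,31.5,21.8
Cx. pipiens/restuans,180,5.9,31.0,22.0
Ps. ferox,193,6.3,28.9,21.5
Oc. excrucians,198,6.5,29.6,21.8
Cs. melanura,203,6.6,33.2,22.6
Cq. perturbans,229,7.5,32.4,21.9
Ae. vexans,229,7.5,30.6,21.7
An. punctipennis,242,7.9,32.6,22.2
An. quadrimaculatus,247,8.1,34.4,21.8
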