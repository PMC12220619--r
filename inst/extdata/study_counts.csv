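species,abundance_pre,abundance_d1,abundance_d2,scanned_pre,scanned_d1,scanned_d2
Ae. cinereus,369,302,264,178,125,118
Ae. vexans,74,63,88,66,52,87
An. punctipennis,119,101,95,105,86,85
An. quadrimaculatus,23,16,16,15,15,13
Cq. perturbans,1011,795,1179,121,124,119
Cs. melanura,177,108,182,116,109,134
Cx. pipiens/restuans,2391,1723,2570,320,117,115
Oc. abserratus,35,23,22,34,19,21
Oc. canadensis,1274,810,794,189,117,115
Oc. excrucians,36,16,10,30,9,9
Ps. ferox,239,70,126,147,69,121
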