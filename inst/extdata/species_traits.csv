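species,trend_group,habitat_water,voltinism,max_flight_km
Ae. vexans,A,temporary,multivoltine,5.73
Cq. perturbans,A,permanent,univoltine,3.40
Cs. melanura,A,permanent,multivoltine,9.80
Ae. cinereus,B,temporary,univoltine,1.60
Oc. abserratus,B,permanent,univoltine,
Oc. canadensis,B,temporary,univoltine,
An. quadrimaculatus,C,permanent,multivoltine,3.42
Oc. excrucians,C,permanent,univoltine,10.00
An. punctipennis,D,permanent,multivoltine,16.90
Cx. pipiens/restuans,D,temporary,multivoltine,9.70
Ps. ferox,D,temporary,multivoltine,2.50
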