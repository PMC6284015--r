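stage,older_ma,younger_ma,period
Tournaisian,358.9,346.7,Carboniferous
Visean,346.7,330.9,Carboniferous
Serpukhovian,330.9,323.2,Carboniferous
Bashkirian,323.2,315.2,Carboniferous
Moscovian,315.2,307.0,Carboniferous
Kasimovian,307.0,303.7,Carboniferous
Gzhelian,303.7,298.9,Carboniferous
Asselian,298.9,293.52,Permian
Sakmarian,293.52,290.1,Permian
Artinskian,290.1,283.5,Permian
Kungurian,283.5,273.01,Permian
Roadian,273.01,266.9,Permian
Wordian,266.9,264.28,Permian
Capitanian,264.28,259.51,Permian
Wuchiapingian,259.51,254.14,Permian
Changhsingian,254.14,251.902,Permian
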