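,WNA,ENA,NSA,SSA,WEu,EEu,EAs,NAf,SAf,Mad,Ind,Aus,Ant
WNA,1,0,1,0,0,0,0,0,0,0,0,0,0
ENA,0,1,0,0,1,0,0,0,0,0,0,0,0
NSA,1,0,1,1,0,0,0,1,0,0,0,0,0
SSA,0,0,1,1,0,0,0,0,1,0,0,0,1
WEu,0,1,0,0,1,1,0,1,0,0,0,0,0
EEu,0,0,0,0,1,1,1,0,0,0,0,0,0
EAs,0,0,0,0,0,1,1,0,0,0,1,1,0
NAf,0,0,1,0,1,0,0,1,1,0,0,0,0
SAf,0,0,0,1,0,0,0,1,1,1,0,0,1
Mad,0,0,0,0,0,0,0,0,1,1,1,0,0
Ind,0,0,0,0,0,0,1,0,0,1,1,1,1
Aus,0,0,0,0,0,0,1,0,0,0,1,1,1
Ant,0,0,0,1,0,0,0,0,1,0,1,1,1
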