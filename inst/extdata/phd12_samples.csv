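barcode,target,round,wash,amplified
AAA,parental,0,none,false
ATC,ubiquitin,1,slow,false
AGG,ubiquitin,2,slow,false
ACT,ubiquitin,3,slow,false
ACG,ubiquitin,1,slow,true
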