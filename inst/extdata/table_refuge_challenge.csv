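team,score,dsc_cup,rank_cup,dsc_disc,rank_disc,delta,rank_delta
CUHKMED,1.75,0.8826,2,0.9602,2,0.0450,2
Masker,2.50,0.8837,1,0.9464,8,0.0414,1
BUCT,3.00,0.8728,4,0.9525,4,0.0456,3
proposed,4.10,0.8786,3,0.9628,1,0.0520,7
NKSG,4.60,0.8643,6,0.9488,6,0.0465,4
VRT,5.40,0.8600,7,0.9532,3,0.0525,8
AIML,5.45,0.8519,8,0.9505,5,0.0469,5
Mammoth,7.10,0.8667,5,0.9361,11,0.0526,9
SMILEDeepDR,7.45,0.8367,9,0.9386,10,0.0488,6
NIGHTOwl,8.60,0.8257,11,0.9487,7,0.0563,10
SDSAIRC,9.15,0.8315,10,0.9436,9,0.0674,11
Cvblab,11.00,0.7728,12,0.9077,12,0.0798,12
Winter_Fell,12.00,0.6861,13,0.8772,13,0.1536,13
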