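baseline,cae,bmal,db_plus,dsc_cup,dsc_disc,delta
1,0,0,0,0.8427,0.9387,0.0785
1,1,0,0,0.8526,0.9425,0.0702
1,0,1,0,0.8652,0.9514,0.0721
1,1,1,0,0.8725,0.9610,0.0562
1,1,1,1,0.8786,0.9628,0.0520
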