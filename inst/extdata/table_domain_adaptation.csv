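method,dsc_cup_drishti,dsc_disc_drishti,delta_drishti,dsc_cup_rimone,dsc_disc_rimone,delta_rimone
BEAL,0.862,0.961,NA,0.810,0.898,NA
DoFE,0.835,0.955,NA,0.800,0.893,NA
CADA,0.840,0.890,0.111,0.640,0.766,0.087
CFEA,0.827,0.887,0.113,0.635,0.751,0.095
AdaptSegNet,0.826,0.881,0.118,0.627,0.737,0.102
DAE,0.831,0.940,NA,0.790,0.891,NA
SRDA,0.807,0.962,NA,0.776,0.894,NA
proposed,0.857,0.962,0.083,0.791,0.898,0.082
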