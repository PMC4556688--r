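group,measure,mean,sd
Control,transition_C,71.99,0.77
Control-CXL,transition_C,74.55,0.25
Control-CXL+Col,transition_C,73.84,0.72
COLG,transition_C,71.22,0.20
COLG-CXL,transition_C,74.31,0.53
COLG-CXL+Col,transition_C,73.96,0.65
ChaseABC,transition_C,70.70,0.68
ChaseABC-CXL,transition_C,74.95,0.72
ChaseABC-CXL+Col,transition_C,73.68,0.67
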