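group,measure,mean,sd
Control,cct_um,362,12.0
Control-CXL,cct_um,348,7.5
Control-CXL+Col,cct_um,355,6.5
COLG,cct_um,331,10.5
COLG-CXL,cct_um,325,5.0
COLG-CXL+Col,cct_um,338,8.5
ChaseABC,cct_um,316,6.5
ChaseABC-CXL,cct_um,235,13.0
ChaseABC-CXL+Col,cct_um,265,10.0
Control,swelled_cct_um,718,7.0
Control-CXL,swelled_cct_um,683,8.5
Control-CXL+Col,swelled_cct_um,678,6.0
COLG,swelled_cct_um,791,9.5
COLG-CXL,swelled_cct_um,765,9.0
COLG-CXL+Col,swelled_cct_um,722,7.5
ChaseABC,swelled_cct_um,844,12.5
ChaseABC-CXL,swelled_cct_um,663,10.5
ChaseABC-CXL+Col,swelled_cct_um,552,11.0
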