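group,measure,mean,sd
Control,diameter_nm,40.67,0.92
Control-CXL,diameter_nm,42.38,0.62
Control-CXL+Col,diameter_nm,40.82,0.53
COLG,diameter_nm,36.37,2.15
COLG-CXL,diameter_nm,37.21,3.44
COLG-CXL+Col,diameter_nm,37.03,2.18
ChaseABC,diameter_nm,40.45,3.81
ChaseABC-CXL,diameter_nm,41.55,2.02
ChaseABC-CXL+Col,diameter_nm,41.57,1.53
Control,nn_distance_nm,72.3,0.89
Control-CXL,nn_distance_nm,69.4,2.01
Control-CXL+Col,nn_distance_nm,58.7,2.81
COLG,nn_distance_nm,75.4,1.22
COLG-CXL,nn_distance_nm,62.4,2.78
COLG-CXL+Col,nn_distance_nm,60.7,3.22
ChaseABC,nn_distance_nm,78.8,4.00
ChaseABC-CXL,nn_distance_nm,63.8,4.67
ChaseABC-CXL+Col,nn_distance_nm,61.8,4.13
Control,density,18.0,0.47
Control-CXL,density,24.6,0.53
Control-CXL+Col,density,25.5,0.92
COLG,density,13.9,1.56
COLG-CXL,density,23.5,1.38
COLG-CXL+Col,density,24.2,1.42
ChaseABC,density,13.1,0.97
ChaseABC-CXL,density,25.0,2.06
ChaseABC-CXL+Col,density,25.7,3.22
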