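factor,response,pair,value
A,GP,AB,23.2
A,GP,AC,23.1
A,PL,AB,21.1
A,PL,AC,21.0
A,RL,AB,21.8
A,RL,AC,21.2
B,GP,AB,40.6
B,GP,BC,40.7
B,PL,AB,37.3
B,PL,BC,37.8
B,RL,AB,39.0
B,RL,BC,39.1
C,GP,AC,304.2
C,GP,BC,303.6
C,PL,AC,347.4
C,PL,BC,350.9
C,RL,AC,348.0
C,RL,BC,348.4
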