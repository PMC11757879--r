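id,reference,method,group
A,1214.9,1099.6,running
B,1173.4,1026.5,running
C,1102,1058.8,running
D,975,1052.1,running
E,842.9,1071.6,running
F,1280.8,1047.3,running_walking
G,1275.4,1020.7,running_walking
H,893.2,990.4,running_walking
I,1067.5,1152.1,running_walking
J,1285.2,1079.4,running_walking
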