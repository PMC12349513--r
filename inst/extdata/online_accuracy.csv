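participant,mutual_cmd13,individual_cmd13,mutual_cmd46,individual_cmd46
1,100.0,88.9,95.8,81.5
2,100.0,88.9,91.7,81.5
3,91.8,92.6,75.0,81.5
4,79.2,96.3,79.7,92.6
5,100.0,100.0,95.8,92.6
6,83.3,90.0,79.7,88.6
7,87.5,91.2,75.0,85.2
8,100.0,88.9,91.7,77.8
9,95.8,92.3,95.8,85.2
10,91.7,94.9,83.3,77.8
11,100.0,97.4,87.5,92.6
12,95.8,94.9,79.7,85.2
13,87.5,100.0,70.8,88.9
14,95.8,100.0,91.7,88.9
15,100.0,96.3,75.0,92.6
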