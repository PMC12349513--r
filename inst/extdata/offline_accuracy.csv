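participant,relpsd_cb1,relpsd_cb2,relpsd_cb3,psd_cb1,psd_cb2,psd_cb3
1,88.9,81.9,80.6,77.8,79.2,75.0
2,97.2,86.1,90.3,86.1,77.8,83.3
3,80.6,86.1,81.9,83.3,83.3,84.7
4,80.6,77.8,80.6,77.8,76.4,77.8
5,88.9,90.3,88.9,88.9,81.9,87.5
6,86.1,88.9,83.3,81.9,76.4,76.4
7,75.0,80.6,81.9,88.9,83.3,80.6
8,88.9,86.1,83.3,77.8,80.6,77.8
9,83.3,83.3,84.7,79.2,80.6,75.0
10,94.4,93.1,90.3,83.3,79.2,80.6
11,84.7,91.7,84.7,87.5,83.3,83.3
12,83.3,86.1,83.3,76.4,76.4,83.3
13,81.9,77.8,80.6,88.9,81.9,75.0
14,87.5,80.6,81.9,81.9,80.6,79.2
15,81.9,81.9,81.9,81.9,79.2,73.6
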