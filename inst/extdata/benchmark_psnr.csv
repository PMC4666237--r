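patient,n_images,he,opening,closing,clahe,hcha
1,19,18.09,20.46,19.75,17.35,19.39
2,22,23.30,19.21,19.45,18.09,18.67
3,20,19.00,17.32,17.37,18.11,19.18
4,22,16.71,19.42,19.03,16.68,19.52
5,26,11.47,21.11,19.22,17.59,21.35
6,30,10.69,20.01,18.49,18.17,22.19
7,15,21.05,18.62,18.45,17.36,19.54
8,18,12.38,20.54,19.31,15.00,20.97
9,17,15.26,20.18,19.36,18.15,19.69
10,22,13.14,21.76,20.57,17.11,21.27
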