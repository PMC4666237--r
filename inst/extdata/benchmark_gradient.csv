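patient,n_images,he,opening,closing,clahe,hcha
1,19,22.51,9.78,8.89,28.81,19.48
2,22,28.31,8.91,9.42,37.93,24.55
3,20,24.27,11.42,10.27,30.76,27.34
4,22,26.97,10.50,9.66,35.47,21.17
5,26,26.36,10.28,7.32,26.76,16.47
6,30,30.92,10.42,6.84,28.11,18.50
7,15,25.70,10.61,10.04,35.37,25.37
8,18,28.36,8.86,7.44,33.22,17.12
9,17,23.52,11.04,9.02,29.21,21.90
10,22,21.84,9.05,7.62,26.99,16.18
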