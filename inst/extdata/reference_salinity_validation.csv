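no,measured,mlr_inverted,mlr_error,mlr_relative_error,bp_inverted,bp_error,bp_relative_error
1,8.18,14.70,6.52,44.34,8.771,0.735,8.99
2,1.53,10.96,9.43,86.04,1.490,0.068,4.47
3,12.4,6.89,-5.51,-79.95,1.660,1.592,12.84
4,0.08,3.12,3.04,97.43,0.077,-0.003,-4.00
5,0.22,4.60,4.38,95.22,0.129,-0.091,-41.59
6,0.14,3.26,3.12,95.71,0.151,0.011,7.78
7,0.07,4.37,4.30,98.40,0.134,0.057,80.90
8,0.04,3.56,3.52,98.88,0.008,0.014,34.27
9,0.06,2.98,2.92,97.99,0.027,-0.017,-28.92
10,0.08,3.61,3.53,97.78,0.042,-0.038,-47.44
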