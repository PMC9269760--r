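rho_a,T,S,theta_s,theta_v,phi,tau
0.13766,0.83489,0.06554,0,0,0,0.00010
0.13766,0.83489,0.06554,0,0,12,0.00010
0.13766,0.83489,0.06554,0,0,24,0.00010
0.13766,0.83489,0.06554,0,0,36,0.00010
0.17874,0.73011,0.08739,6,3,48,0.25
0.17874,0.73011,0.08706,6,3,60,0.25
0.17874,0.73011,0.08671,6,3,72,0.25
0.17874,0.73011,0.08637,6,3,84,0.25
0.26870,0.28913,0.17870,24,30,96,1.50
0.26870,0.28913,0.17731,24,30,108,1.50
0.26870,0.28913,0.17640,24,30,120,1.50
0.26870,0.28913,0.17588,24,30,132,1.50
0.28252,0.12120,0.32403,60,60,144,1.95
0.28252,0.12120,0.33546,60,60,156,1.95
0.28252,0.12120,0.34339,60,60,168,1.95
0.28252,0.12120,0.34623,60,60,180,1.95
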