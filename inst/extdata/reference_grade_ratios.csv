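year,grade,area_km2,ratio_pct
2000,Worst,2.15,13.91
2000,Worse,8.99,58.07
2000,Medium,3.71,23.98
2000,Good,0.47,3.03
2000,Excellent,0.16,1.02
2007,Worst,3.77,24.34
2007,Worse,7.06,45.61
2007,Medium,3.95,25.50
2007,Good,0.66,4.27
2007,Excellent,0.04,0.28
2014,Worst,0.04,0.27
2014,Worse,1.37,8.86
2014,Medium,6.42,41.44
2014,Good,5.83,37.66
2014,Excellent,1.82,11.76
2019,Worst,1.26,8.17
2019,Worse,2.40,15.49
2019,Medium,3.25,21.01
2019,Good,5.57,35.96
2019,Excellent,3.00,19.37
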