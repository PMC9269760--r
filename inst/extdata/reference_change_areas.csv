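period,class,area_km2,ratio_pct
2000-2007,Worse,7.42,47.93
2000-2007,Unchanged,4.84,31.26
2000-2007,Better,3.22,20.81
2007-2014,Worse,2.90,18.75
2007-2014,Unchanged,1.29,8.31
2007-2014,Better,11.29,72.94
2014-2019,Worse,3.21,20.71
2014-2019,Unchanged,3.10,20.02
2014-2019,Better,9.17,59.27
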