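reactor,setup,duration,sulfate_water,h2_total,ratio_water_printed,ratio_total_printed
1,serial,108,10.1,49.1,4.9,2.7
2,serial,108,8.1,49.0,6.1,3.0
3,parallel,73,16.1,32.6,2.0,1.3
4,parallel,79,22.9,33.1,1.4,1.1
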