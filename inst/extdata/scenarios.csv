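scenario,obesity_change_per_5y,year,prevalence_pct
A,5,2015,8.6
A,5,2020,9.1
A,5,2030,10.1
A,5,2040,11.1
A,5,2050,12.0
A,5,2060,12.8
baseline,1,2015,8.6
baseline,1,2020,9.0
baseline,1,2030,9.6
baseline,1,2040,10.1
baseline,1,2050,10.5
baseline,1,2060,10.8
B,0,2015,8.6
B,0,2020,8.9
B,0,2030,9.5
B,0,2040,9.9
B,0,2050,10.2
B,0,2060,10.3
C,-3,2015,8.6
C,-3,2020,8.8
C,-3,2030,9.1
C,-3,2040,9.3
C,-3,2050,9.3
C,-3,2060,9.2
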