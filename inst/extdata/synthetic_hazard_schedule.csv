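age_start,age_end,incidence_per_100k,mortality_per_100k
20,25,4.3,40
25,30,17.2,45
30,35,42.9,55
35,40,85.9,70
40,45,150.3,100
45,50,204,160
50,55,214.7,260
55,60,204,450
60,65,182.5,800
65,70,161.1,1400
70,75,139.6,2500
75,80,118.1,4200
80,85,96.6,7000
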