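midpoint_age,sex,deaths,death_probability,ex,yll_thousands
0,male,3,0.0063,76.0,0.22
1,male,1,0.0004,75.5,0.08
10,male,10,0.0001,66.5,0.67
20,male,68,0.0011,56.9,3.87
30,male,396,0.0019,47.7,18.87
40,male,1094,0.0025,38.6,42.18
50,male,3009,0.0050,29.7,89.28
60,male,6988,0.0115,21.6,150.80
70,male,11479,0.0229,14.4,165.18
80,male,12961,0.0582,8.3,107.32
85,male,11566,0.0979,5.9,68.12
0,female,2,0.0052,81.0,0.16
1,female,2,0.0003,80.4,0.16
10,female,2,0.0001,71.5,0.14
20,female,38,0.0004,61.6,2.34
30,female,187,0.0008,52.0,9.71
40,female,430,0.0014,42.5,18.26
50,female,1229,0.0031,33.2,40.83
60,female,3598,0.0069,24.6,88.37
70,female,6881,0.0153,16.5,113.81
80,female,10650,0.0428,9.7,103.09
85,female,17647,0.0743,7.0,122.65
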