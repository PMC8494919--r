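subject,sex,bmi,age,waist,height,weight,excluded,exclusion_reason
1,M,34.4,41,116,175,105.2,FALSE,
2,F,49.7,67,131,158.5,124.7,FALSE,
3,F,39.0,63,123.5,160,99.8,FALSE,
4,F,33.0,35,116.5,168.9,94.1,TRUE,electrode_malfunction
5,F,30.6,61,92.5,155.5,73.9,FALSE,
6,F,36.3,27,103.5,163.5,97.2,FALSE,
7,F,29.3,42,91,155,70.3,FALSE,
8,F,37.8,60,115.5,174,114.5,FALSE,
9,F,32.0,36,113,170,92.5,FALSE,
10,F,34.3,36,101.5,152,79.2,FALSE,
11,M,27.9,47,95,178,88.5,FALSE,
12,F,46.8,39,130,160,119.8,FALSE,
13,F,38.9,48,114,168,109.9,FALSE,
14,F,25.5,74,96,163.5,68.2,TRUE,renal_failure
15,F,33.7,26,95,153,78.9,FALSE,
16,F,27.4,33,93.5,170.5,79.8,FALSE,
17,M,27.1,47,103,178,85.7,FALSE,
18,M,46.9,57,141.5,177.5,147.7,TRUE,leukemia
19,F,29.8,30,102,180.3,96.9,FALSE,
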