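date,tmax,tmean,tmin,humidity
2003-07-17,32.25,27.75,24.25,78
2003-07-18,31.82,27.32,23.82,78
2003-07-19,31.84,27.34,23.84,78
2003-07-20,35.6,31.1,27.6,73
2003-07-21,36.54,32.04,28.54,71
2003-07-22,37.56,33.06,29.56,70
2003-07-23,38.18,33.68,30.18,69
2003-07-24,38.55,34.05,30.55,68
2003-07-25,39.21,34.71,31.21,67
2003-07-26,39.54,35.04,31.54,67
2003-07-27,39.51,35.01,31.51,67
2003-07-28,39.88,35.38,31.88,66
2003-07-29,40,35.5,32,66
2003-07-30,39.83,35.33,31.83,66
2003-07-31,39.95,35.45,31.95,66
2003-08-01,39.17,34.67,31.17,67
2003-08-02,39.09,34.59,31.09,67
2003-08-03,38.8,34.3,30.8,68
2003-08-04,38.08,33.58,30.08,69
2003-08-05,37.27,32.77,29.27,70
2003-08-06,36.38,31.88,28.38,71
2003-08-07,35.6,31.1,27.6,73
2003-08-08,31.81,27.31,23.81,78
2003-08-09,32.14,27.64,24.14,78
2003-08-10,31.93,27.43,23.93,78
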