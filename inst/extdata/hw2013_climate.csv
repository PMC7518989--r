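date,tmax,tmean,tmin,humidity
2013-07-13,31.98,27.48,23.98,78
2013-07-14,32.27,27.77,24.27,78
2013-07-15,32.17,27.67,24.17,78
2013-07-16,36.72,32.22,28.72,71
2013-07-17,37.35,32.85,29.35,70
2013-07-18,38.54,34.04,30.54,68
2013-07-19,39.55,35.05,31.55,67
2013-07-20,39.98,35.48,31.98,66
2013-07-21,40.36,35.86,32.36,65
2013-07-22,40.39,35.89,32.39,65
2013-07-23,40.5,36,32.5,65
2013-07-24,38.86,34.36,30.86,68
2013-07-25,38.45,33.95,30.45,68
2013-07-26,38.81,34.31,30.81,68
2013-07-27,39.97,35.47,31.97,66
2013-07-28,38.62,34.12,30.62,68
2013-07-29,37.59,33.09,29.59,70
2013-07-30,36.76,32.26,28.76,71
2013-07-31,31.75,27.25,23.75,78
2013-08-01,31.9,27.4,23.9,78
2013-08-02,32.03,27.53,24.03,78
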