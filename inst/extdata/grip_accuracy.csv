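subject,feature,mave,rms,rho
1,MAV,0.69,0.89,99.46
1,VAR,1.12,1.36,98.75
1,ZC,1.87,2.85,94.72
1,WA,1.06,1.61,98.27
2,MAV,0.55,0.73,99.62
2,VAR,1.07,1.36,98.64
2,ZC,1.70,2.76,94.79
2,WA,0.84,1.27,98.85
3,MAV,0.63,0.79,99.58
3,VAR,1.03,1.28,98.91
3,ZC,1.82,2.82,94.89
3,WA,1.06,1.53,98.42
4,MAV,0.63,0.82,99.38
4,VAR,1.10,1.41,98.20
4,ZC,1.43,2.49,94.64
4,WA,0.77,1.28,98.56
5,MAV,0.62,0.77,99.56
5,VAR,1.12,1.40,98.51
5,ZC,1.83,3.03,93.13
5,WA,0.97,1.53,98.29
6,MAV,0.54,0.79,99.56
6,VAR,0.85,1.24,98.89
6,ZC,1.44,2.63,95.08
6,WA,0.84,1.44,98.53
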