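subject,feature,direction,mave,rms,rho
1,MAV,x,0.42,0.70,99.13
1,MAV,y,0.44,0.78,99.05
1,MAV,z,0.22,0.32,96.47
1,VAR,x,0.53,0.98,98.31
1,VAR,y,0.49,0.89,98.81
1,VAR,z,0.24,0.36,95.74
1,ZC,x,1.78,3.15,86.56
1,ZC,y,1.98,3.19,86.34
1,ZC,z,0.45,0.71,85.51
1,WA,x,0.48,0.76,99.02
1,WA,y,0.50,1.02,98.45
1,WA,z,0.18,0.26,97.68
2,MAV,x,0.38,0.68,98.44
2,MAV,y,0.46,0.78,99.06
2,MAV,z,0.34,0.50,98.65
2,VAR,x,0.45,0.83,97.75
2,VAR,y,0.52,0.87,98.86
2,VAR,z,0.37,0.58,98.24
2,ZC,x,1.18,2.03,86.65
2,ZC,y,1.66,2.75,89.59
2,ZC,z,0.61,1.07,95.70
2,WA,x,0.43,0.74,98.24
2,WA,y,0.51,1.02,98.44
2,WA,z,0.28,0.44,99.03
3,MAV,x,0.28,0.48,96.33
3,MAV,y,0.47,0.83,98.95
3,MAV,z,0.60,1.04,97.01
3,VAR,x,0.39,0.79,90.22
3,VAR,y,0.56,0.88,98.82
3,VAR,z,1.11,1.85,90.34
3,ZC,x,0.42,1.08,79.14
3,ZC,y,1.02,1.86,95.28
3,ZC,z,0.69,1.11,97.54
3,WA,x,0.30,0.54,95.56
3,WA,y,0.45,0.82,98.99
3,WA,z,0.64,1.22,95.80
4,MAV,x,0.22,0.29,99.55
4,MAV,y,0.33,0.64,98.55
4,MAV,z,0.64,1.11,96.48
4,VAR,x,0.31,0.42,99.05
4,VAR,y,0.43,0.77,97.96
4,VAR,z,1.12,1.92,89.43
4,ZC,x,0.51,0.93,96.26
4,ZC,y,1.09,2.07,86.10
4,ZC,z,0.77,1.18,96.97
4,WA,x,0.26,0.41,99.15
4,WA,y,0.34,0.71,98.24
4,WA,z,0.66,1.31,94.98
5,MAV,x,0.28,0.44,99.63
5,MAV,y,0.21,0.48,96.05
5,MAV,z,0.54,0.98,97.13
5,VAR,x,0.42,0.76,98.90
5,VAR,y,0.27,0.52,95.37
5,VAR,z,1.04,1.82,90.42
5,ZC,x,0.69,1.16,98.29
5,ZC,y,0.54,1.32,64.15
5,ZC,z,0.80,1.32,95.73
5,WA,x,0.36,0.64,99.19
5,WA,y,0.24,0.65,92.87
5,WA,z,0.56,1.12,96.28
6,MAV,x,0.41,0.79,98.87
6,MAV,y,0.26,0.48,99.26
6,MAV,z,0.50,0.89,97.63
6,VAR,x,0.57,1.17,97.54
6,VAR,y,0.36,0.74,98.23
6,VAR,z,0.91,1.65,92.44
6,ZC,x,1.29,2.21,94.03
6,ZC,y,1.35,2.44,80.13
6,ZC,z,0.82,1.35,95.51
6,WA,x,0.53,0.95,98.39
6,WA,y,0.35,0.76,98.16
6,WA,z,0.50,0.98,97.06
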