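variable,INT1,DEP1,ANX1,HOS1,PHO1,PSY1,INT2,DEP2,ANX2,HOS2,PHO2,PSY2
INT1,1,0.74,0.42,0.39,0.48,0.49,0.38,0.35,0.27,0.23,0.26,0.33
DEP1,0.74,1,0.44,0.27,0.49,0.48,0.29,0.26,0.21,0.14,0.18,0.28
ANX1,0.42,0.44,1,0.29,0.43,0.5,0.25,0.22,0.31,0.16,0.24,0.25
HOS1,0.39,0.27,0.29,1,0.23,0.16,0.2,0.29,0.23,0.42,0.18,0.23
PHO1,0.48,0.49,0.43,0.23,1,0.27,0.19,0.18,0.22,0.08,0.35,0.26
PSY1,0.49,0.48,0.5,0.16,0.27,1,0.34,0.32,0.27,0.21,0.16,0.38
INT2,0.38,0.29,0.25,0.2,0.19,0.34,1,0.73,0.75,0.64,0.64,0.82
DEP2,0.35,0.26,0.22,0.29,0.18,0.32,0.73,1,0.81,0.77,0.74,0.82
ANX2,0.27,0.21,0.31,0.23,0.22,0.27,0.75,0.81,1,0.71,0.74,0.84
HOS2,0.23,0.14,0.16,0.42,0.08,0.21,0.64,0.77,0.71,1,0.63,0.68
PHO2,0.26,0.18,0.24,0.18,0.35,0.16,0.64,0.74,0.74,0.63,1,0.72
PSY2,0.33,0.28,0.25,0.23,0.26,0.38,0.82,0.82,0.84,0.68,0.72,1
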