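name,unit,control_mean,control_sd,case_mean,case_sd,lower_bound,missing_rate
MO#,10^3/uL,0.53,0.185,0.619,0.237,0,0
HCT,%,44.356,4.207,42.358,4.24,0,0
HGB,g/dL,15.256,1.76,14.371,1.726,0,0
RBC,10^6/uL,5.112,0.498,4.91,0.471,0,0
Iron,ug/dL,53.547,32.252,73.258,40.752,0,0
Calcium,mg/dL,9.744,0.182,9.576,0.371,0,0
Glucose,mg/dL,93.312,26.932,83.039,10.139,0,0
Potassium,mmol/L,4.408,0.171,4.303,0.305,0,0
MO%,%,7.451,1.876,8.153,2.024,0,0
MCHC,g/dL,34.106,1.369,33.602,1.461,0,0
BA#,10^3/uL,0.016,0.018,0.021,0.017,0,0
BA%,%,0.21,0.225,0.279,0.222,0,0
GGT,U/L,22.385,6.636,30.212,37.351,0,0
Triglyceride,mg/dL,109.932,33.427,142.409,153.837,0,0
RDW-SD,fL,40.514,2.654,41.342,2.977,0,0
IG%,%,0.316,0.218,0.389,0.284,0,0
IG#,10^3/uL,0.025,0.021,0.031,0.024,0,0
Sodium,mmol/L,139.807,1.048,140.241,1.969,0,0
MCH,pg,29.76,2.202,29.152,2.199,0,0
RDW-CV,%,12.94,1.15,13.215,1.16,0,0
NRBC#,10^3/uL,0.0,0.001,0.0,0.002,0,0
NE%,%,58.646,8.187,56.64,10.77,0,0
PLT,10^3/uL,252.594,54.953,241.248,57.168,0,0
Creatinine,mg/dL,0.802,0.144,0.83,0.152,0,0
NRBC%,%,0.001,0.014,0.004,0.022,0,0
AST,U/L,22.859,10.654,24.931,15.562,0,0
PCT,%,0.262,0.049,0.254,0.056,0,0
WBC,10^3/uL,7.351,2.72,7.7,2.204,0,0
MPV,fL,10.315,0.805,10.425,0.931,0,0
MCV,fL,86.831,4.376,86.275,4.605,0,0
LY%,%,31.073,7.887,32.135,9.922,0,0
ALP,U/L,76.422,20.669,79.271,29.164,0,0
EO#,10^3/uL,0.149,0.13,0.163,0.144,0,0
NE#,10^3/uL,4.449,1.554,4.601,1.888,0,0
LDL Cholesterol,mg/dL,90.688,12.292,89.084,24.059,0,0
LY#,10^3/uL,2.323,1.592,2.428,0.782,0,0
eGFR,mL/min/1.73m2,118.88,12.021,119.621,9.876,0,0
PDW,fL,12.056,1.668,12.159,2.042,0,0
EO%,%,2.058,1.744,2.144,1.924,0,0
HDL Cholesterol,mg/dL,43.37,4.677,43.665,8.12,0,0
ALT,U/L,24.953,19.345,25.778,18.138,0,0
Urea,mg/dL,24.536,6.078,24.281,6.683,0,0
Total Cholesterol,mg/dL,159.719,16.99,160.616,34.498,0,0
BUN,mg/dL,11.401,2.867,11.31,3.154,0,0
NLR,ratio,2.082,0.923,2.096,1.351,0,0
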