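cause,lag,stratum,pct,lo,hi
cvd,lag0,total,1.42,0.92,1.92
cvd,lag0,urban,1.51,0.82,2.21
cvd,lag0,rural,1.34,0.58,2.10
cvd,lag0-4,total,0.50,-0.47,1.49
cvd,lag0-4,urban,1.43,0.26,2.62
cvd,lag0-4,rural,-0.52,-1.89,0.88
coronary,lag0,total,1.47,0.59,2.35
coronary,lag0,urban,0.97,-0.11,2.07
coronary,lag0,rural,2.18,0.86,3.51
coronary,lag0-4,total,0.98,-0.67,2.65
coronary,lag0-4,urban,2.05,-0.13,4.28
coronary,lag0-4,rural,-0.46,-2.66,1.79
ischemic_stroke,lag0,total,1.57,0.64,2.51
ischemic_stroke,lag0,urban,1.92,0.56,3.29
ischemic_stroke,lag0,rural,1.22,-0.11,2.57
ischemic_stroke,lag0-4,total,1.68,0.08,3.29
ischemic_stroke,lag0-4,urban,2.22,-0.08,4.59
ischemic_stroke,lag0-4,rural,1.19,-1.00,3.42
hypertension,lag0,total,2.54,1.21,3.88
hypertension,lag0,urban,2.49,0.50,4.53
hypertension,lag0,rural,2.45,0.61,4.32
hypertension,lag0-4,total,0.46,-1.97,2.94
hypertension,lag0-4,urban,0.11,-3.71,4.08
hypertension,lag0-4,rural,0.41,-2.69,3.61
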