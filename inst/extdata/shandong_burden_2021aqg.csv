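stratum,cause,outcome,an,an_lo,an_hi,total
urban,cvd,admissions,5447,2990,7859,160652
rural,cvd,admissions,4765,2099,7376,142565
urban,cvd,days,81801,44831,118191,3032005
rural,cvd,days,42131,18562,65212,1270493
urban,cvd,expenses,60121,33002,86729,1750769
rural,cvd,expenses,32875,14483,50886,1000098
urban,coronary,admissions,1171,-133,2434,50487
rural,coronary,admissions,1893,769,2977,34681
urban,coronary,days,12728,-1444,26501,618506
rural,coronary,days,15019,6098,23616,276533
urban,coronary,expenses,13950,-1584,29011,607536
rural,coronary,expenses,14366,5833,22592,264723
urban,ischemic_stroke,admissions,1449,433,2426,30802
rural,ischemic_stroke,admissions,1198,-108,2455,37276
urban,ischemic_stroke,days,19803,5915,33202,473765
rural,ischemic_stroke,days,11809,-1064,24207,371029
urban,ischemic_stroke,expenses,14575,4357,24413,320728
rural,ischemic_stroke,expenses,7302,-658,14969,232727
urban,hypertension,admissions,1272,265,2232,27054
rural,hypertension,admissions,1066,274,1819,18095
urban,hypertension,days,22999,4760,40576,628622
rural,hypertension,days,8104,2083,13831,138562
urban,hypertension,expenses,8435,1756,14795,177565
rural,hypertension,expenses,3372,867,5756,5835
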