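scope,trait,sigma2_prov,sigma2_ind,sigma2_res,r_printed,significant
b03,Rt,NA,0.011,0.737,0.015,FALSE
b03,Rc,NA,0.043,0.926,0.045,FALSE
b03,Rs,NA,0.000,0.967,NA,FALSE
b03,rRs,NA,0.053,0.614,0.080,FALSE
d04,Rt,NA,0.000,0.929,0.000,FALSE
d04,Rc,NA,0.000,0.819,NA,FALSE
d04,Rs,NA,0.000,0.876,0.000,FALSE
d04,rRs,NA,0.000,0.893,0.000,FALSE
R06,Rt,NA,0.198,0.650,0.233,TRUE
R06,Rc,NA,0.035,0.557,0.059,FALSE
R06,Rs,NA,0.000,1.353,0.000,FALSE
R06,rRs,NA,0.000,0.813,0.000,FALSE
ST,Rt,NA,0.106,1.172,0.083,FALSE
ST,Rc,NA,0.404,0.922,0.305,TRUE
ST,Rs,NA,0.000,0.912,NA,FALSE
ST,rRs,NA,0.120,1.505,0.074,FALSE
X05,Rt,NA,0.071,0.928,0.071,FALSE
X05,Rc,NA,0.013,0.664,0.019,FALSE
X05,Rs,NA,0.000,0.860,NA,FALSE
X05,rRs,NA,0.041,0.734,0.053,FALSE
d14,Rt,NA,0.304,0.575,0.346,TRUE
d14,Rc,NA,0.138,0.560,0.198,TRUE
d14,Rs,NA,0.162,0.767,0.174,TRUE
d14,rRs,NA,0.137,0.498,0.215,TRUE
I19,Rt,NA,0.151,0.636,0.192,TRUE
I19,Rc,NA,0.219,0.648,0.253,TRUE
I19,Rs,NA,0.000,0.812,NA,FALSE
I19,rRs,NA,0.145,0.563,0.205,TRUE
Q14,Rt,NA,0.373,0.584,0.389,TRUE
Q14,Rc,NA,0.149,0.802,0.157,TRUE
Q14,Rs,NA,0.000,1.040,NA,FALSE
Q14,rRs,NA,0.022,0.810,0.027,FALSE
R13,Rt,NA,0.517,0.657,0.440,TRUE
R13,Rc,NA,0.162,1.388,0.105,FALSE
R13,Rs,NA,0.000,1.284,0.000,FALSE
R13,rRs,NA,0.000,1.217,0.000,FALSE
S10,Rt,NA,0.381,0.552,0.408,TRUE
S10,Rc,NA,0.239,0.498,0.324,TRUE
S10,Rs,NA,0.000,1.012,NA,FALSE
S10,rRs,NA,0.083,0.550,0.131,TRUE
Y18,Rt,NA,0.061,0.872,0.065,FALSE
Y18,Rc,NA,0.000,1.155,NA,FALSE
Y18,Rs,NA,0.000,0.957,NA,FALSE
Y18,rRs,NA,0.000,1.381,0.000,FALSE
Overall,Rt,0.022,0.182,0.798,0.182,TRUE
Overall,Rc,0.032,0.129,0.838,0.129,TRUE
Overall,Rs,0.016,0.000,0.983,0.000,FALSE
Overall,rRs,0.014,0.037,0.947,0.037,TRUE
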