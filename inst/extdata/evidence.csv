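parameter_name,direction,n_supporting,n_contradicting,links
f01,1,2,0,
f02,1,0,1,
f03,-1,1,0,
f04,1,3,0,f05
f05,1,0,0,
f06,-1,0,2,
f07,1,1,0,
f08,1,0,0,
f09,-1,2,0,
f10,1,0,1,
f11,1,6,0,
f12,-1,0,0,
f13,1,1,0,
f14,1,0,0,
med_irmph,-1,4,0,
med_xrmph,-1,3,0,
med_dex,-1,2,0,
med_atom,-1,2,1,
intercept,1,0,0,
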