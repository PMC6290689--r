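team,parameter,a,b,pct_printed,reproducible
19,diameter,2.52,2.49,1,TRUE
19,flow_rate,1.84,1.99,8,TRUE
19,velocity,38.5,42.3,10,FALSE
19,reynolds,270,294,9,TRUE
19,poiseuille_wss,4.44,4.91,10,TRUE
19,calculated_wss,4.68,7.41,45,TRUE
19,wss_ratio,1.11,1.51,30,FALSE
19,flow_division,0.57,0.55,4,TRUE
19,awss,2.64,4.05,42,TRUE
19,awss_star,0.597,0.577,4,FALSE
19,mwss,25.5,45.5,56,TRUE
19,mwss_star,5.21,5.9,12,TRUE
19,lsa,0.09,0.091,1,TRUE
19,lsa_star,0.103,0.136,28,TRUE
35,diameter,2.38,2.42,2,TRUE
35,flow_rate,2.72,2.61,4,TRUE
35,velocity,61.1,56.8,7,TRUE
35,reynolds,385,362,6,TRUE
35,poiseuille_wss,8.25,7.63,8,TRUE
35,calculated_wss,9.59,11.7,20,TRUE
35,wss_ratio,1.16,1.57,30,TRUE
35,flow_division,0.63,0.64,NA,FALSE
35,awss,6.06,6.31,4,TRUE
35,awss_star,0.559,0.55,2,TRUE
35,mwss,60.2,64.6,7,TRUE
35,mwss_star,5.79,5.57,4,TRUE
35,lsa,0.045,0.024,60,FALSE
35,lsa_star,0.122,0.153,22,FALSE
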