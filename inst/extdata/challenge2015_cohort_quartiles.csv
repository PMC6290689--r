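parameter,group,n,median,q1,q3,cod_pct_printed,reproducible
diameter,All,27,2.45,2.4,2.56,3.4,FALSE
diameter,high,6,2.5,2.39,2.56,3.5,FALSE
diameter,medium,12,2.47,2.4,2.58,3.4,FALSE
diameter,low,9,2.41,2.32,2.62,6,FALSE
flow_rate,All,25,2.4,1.82,2.91,23,TRUE
flow_rate,high,5,1.99,1.63,2.81,27,TRUE
flow_rate,medium,12,2.3,1.88,2.95,22,TRUE
flow_rate,low,8,2.67,2,3.65,29,TRUE
velocity,All,25,49,38,63.2,25,TRUE
velocity,high,5,42.3,32.8,59.3,29,TRUE
velocity,medium,12,50.9,36.7,62.6,26,TRUE
velocity,low,8,59,40.1,76.8,31,TRUE
reynolds,All,25,345,266,450,26,TRUE
reynolds,high,5,282,227,424,30,TRUE
reynolds,medium,12,334,270,451,25,TRUE
reynolds,low,8,376,288,535,30,TRUE
poiseuille_wss,All,25,6.19,4.48,8.31,30,TRUE
poiseuille_wss,high,5,4.91,3.91,7.16,29,TRUE
poiseuille_wss,medium,12,6.48,4.11,7.61,30,TRUE
poiseuille_wss,low,8,7.94,4.72,9.32,33,TRUE
calculated_wss,All,27,8.29,4.5,12.2,46,TRUE
calculated_wss,high,6,7.04,4.64,10,37,TRUE
calculated_wss,medium,12,9.44,5.41,13.2,42,TRUE
calculated_wss,low,9,6.51,4.05,12.9,52,TRUE
wss_ratio,All,25,1.51,1.2,1.67,16,TRUE
wss_ratio,high,5,1.45,1.23,1.55,11,FALSE
wss_ratio,medium,12,1.6,1.26,1.8,18,TRUE
wss_ratio,low,8,1.37,1.03,1.64,23,TRUE
flow_division,All,25,0.65,0.62,0.69,5,TRUE
flow_division,high,5,0.64,0.56,0.67,9,TRUE
flow_division,medium,12,0.65,0.63,0.69,4,FALSE
flow_division,low,8,0.65,0.62,0.7,6,TRUE
awss,All,27,4.57,2.24,6.31,48,TRUE
awss,high,6,3.26,1.83,5.4,49,TRUE
awss,medium,12,5.63,2.91,6.44,38,TRUE
awss,low,9,2.77,1.43,6.83,65,TRUE
awss_star,All,27,0.561,0.405,0.583,18,TRUE
awss_star,high,6,0.519,0.258,0.634,42,TRUE
awss_star,medium,12,0.561,0.427,0.579,15,TRUE
awss_star,low,9,0.559,0.271,0.649,41,TRUE
mwss,All,27,53.9,22.8,64.6,48,TRUE
mwss,high,6,38,23.3,53.7,39,TRUE
mwss,medium,12,59.2,32.3,64.8,33,TRUE
mwss,low,9,34.5,16.2,69.4,62,TRUE
mwss_star,All,27,5.41,3.83,5.94,22,TRUE
mwss_star,high,6,5.21,4.09,5.53,15,TRUE
mwss_star,medium,12,5.58,3.99,6.37,23,TRUE
mwss_star,low,9,5.58,2.98,6.74,39,TRUE
lsa,All,27,0.083,0.03,0.132,63,TRUE
lsa,high,6,0.091,0.073,0.384,68,TRUE
lsa,medium,12,0.06,0.026,0.099,58,TRUE
lsa,low,9,0.052,0.022,0.431,90,TRUE
lsa_star,All,27,0.145,0.121,0.221,29,TRUE
lsa_star,high,6,0.166,0.125,0.425,55,TRUE
lsa_star,medium,12,0.138,0.12,0.213,28,TRUE
lsa_star,low,9,0.153,0.097,0.475,66,TRUE
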