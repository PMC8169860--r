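county,state,manual_rmse,manual_rrmse_pct,bo_rmse,bo_rrmse_pct,pbo_rmse,pbo_rrmse_pct
Logan,IL,2386,23.03,1442,13.93,1266,12.23
Greene,IN,2820,33.48,1520,18.05,1459,17.32
Keokuk,IA,2612,29.36,1590,17.88,1358,15.26
Boone,IA,2357,23.69,1288,12.95,1076,10.82
Obrien,IA,2482,24.42,992,9.77,865,8.51
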