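quantity,value,how
distance_m,2001.353603,"sum of 4 haversine step lengths, R=6371000 m"
max_nsd_m2,500677.0333,max squared haversine displacement from first fix
mean_speed_ms,0.277965778,mean of step length / 1800 s over the 4 steps
n_fixes,5,count
step_1_m,500.323048,haversine between consecutive fixes
step_2_m,500.377170,haversine between consecutive fixes
step_3_m,500.276216,haversine between consecutive fixes
step_4_m,500.377170,haversine between consecutive fixes
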