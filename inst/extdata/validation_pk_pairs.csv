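# Predicted vs observed PK parameters for the ten olanzapine validation
# simulations (adult single/multiple-dose studies; study 10 is pediatric).
# Cmax in ng/mL, AUC in ng*h/mL, tmax in h; fold_error as printed (pred/obs).
study_id,metric,predicted,observed,fold_error
1,Cmax,8.1,7.8,1.04
1,AUC,298.3,341.4,0.87
1,tmax,4.4,5.0,0.88
2,Cmax,7.2,7.6,0.95
2,AUC,264.1,272.0,0.97
2,tmax,4.9,3.0,1.63
3,Cmax,7.0,5.4,1.30
3,AUC,217.8,236.7,0.92
3,tmax,4.0,7.0,0.57
4,Cmax,13.4,13.2,1.02
4,AUC,426.2,436.9,0.98
4,tmax,4.3,6.0,0.72
5,Cmax,17.2,17.5,0.98
5,AUC,710.3,711.5,1.00
5,tmax,3.9,7.0,0.56
6,Cmax,14.5,16.7,0.87
6,AUC,651.7,629.2,1.04
6,tmax,4.2,5.0,0.84
7,Cmax,14.0,11.2,1.25
7,AUC,436.5,460.3,0.95
7,tmax,4.0,4.8,0.83
8,Cmax,21.0,19.0,1.10
8,AUC,653.1,755.1,0.86
8,tmax,4.0,6.2,0.65
9,Cmax,24.8,19.7,1.26
9,AUC,423.1,388.6,1.09
9,tmax,3.7,6.2,0.60
10,Cmax,92.2,115.6,0.80
10,AUC,1731,2220,0.78
10,tmax,3.0,4.0,0.75
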