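matrix,auc_obs_gd1,auc_est_gd1,auc_obs_gd15,auc_est_gd15,auc_obs_gd20,auc_est_gd20
blood,1.26,1.60,6.71,7.72,7.52,6.53
liver,6.20,4.72,21.22,11.79,15.79,10.75
brain,4.80,3.88,10.28,8.07,7.05,6.86
kidney,12.89,9.45,20.34,21.59,NA,18.26
fat,43.97,37.18,1247.08,1171.88,1260.18,1357.83
mammary,21.23,22.06,606.71,690.07,856.41,840.45
placenta,NA,NA,23.92,12.80,17.67,16.13
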