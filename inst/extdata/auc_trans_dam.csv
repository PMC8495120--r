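matrix,auc_obs_gd1,auc_est_gd1,auc_obs_gd15,auc_est_gd15,auc_obs_gd20,auc_est_gd20
blood,NA,0.42,1.18,0.75,1.04,0.61
liver,NA,NA,NA,1.54,NA,0.95
brain,NA,0.52,0.77,0.71,0.53,0.59
kidney,NA,NA,NA,NA,NA,NA
fat,10.60,10.06,34.41,44.10,61.77,53.29
mammary,NA,3.94,73.20,46.66,37.53,44.18
placenta,NA,NA,NA,1.72,NA,2.26
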