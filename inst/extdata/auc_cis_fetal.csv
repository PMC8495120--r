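matrix,auc_obs,auc_est
fetal_blood,3.35,1.66
fetal_liver,17.86,8.18
fetal_brain,3.83,2.94
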