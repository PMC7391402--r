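parameter,estimate,unit
baseline_v,-0.0321,latent
baseline_s,-0.0347,latent
pmax_v,-0.939,latent
pmax_s,-1.36,latent
tprog_v,12.3,days
tprog_s,14,days
wei,1.6,
drug_v,-0.369,latent
drug_s,-0.634,latent
drift,0,latent/month
iiv_baseline_v,0.986,latent
iiv_baseline_s,1.281,latent
corr_baseline_vs,0.289,
iiv_pmax,1.149,latent
iiv_tprog,0.608,log
iiv_drift,0.006,latent/month
corr_pmax_drift,0.332,
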