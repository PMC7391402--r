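parameter,estimate,unit,rse
baseline,-0.0993,latent,57.1
pmax,-1.22,latent,9.2
tprog,16.2,days,17.5
drug,-0.565,latent,19.3
drift,0,latent/month,NA
wei,1,,NA
pvr_on_baseline,0.00327,latent/mL,24.9
iiv_baseline,1.044,latent,5.5
iiv_pmax,1.349,latent,13.9
iiv_drift,0.009,latent/month,9
iiv_tprog,0.517,log,12.6
corr_baseline_pmax,0.155,,46.3
corr_pmax_drift,0.454,,36.5
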