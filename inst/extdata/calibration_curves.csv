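analyte,wavelength_nm,slope,intercept,r_squared,lod_ugml,loq_ugml,conc_levels_ugml,recovery_pct,recovery_sd,rsd_intraday_pct,rsd_interday_pct
Gallic acid,280,18817,-10155,0.9996,0.014,0.042,0.5;5;25;50,NA,NA,NA,NA
Caffeic acid,320,43686,-19547,0.9998,0.010,0.030,0.5;5;25;50,NA,NA,NA,NA
Apigenin,320,29655,6320.6,0.9999,0.013,0.040,0.5;5;25;50,99.50,2.69,1.16,2.33
Acacetin,320,26463,9248.4,0.9999,0.013,0.041,5;25;50;100,102.19,3.10,0.68,1.54
Luteolin,360,24041,44178,0.9989,0.036,0.109,5;25;50;150,100.47,2.96,1.84,2.70
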