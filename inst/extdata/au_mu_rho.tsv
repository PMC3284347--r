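# Total X-ray mass attenuation coefficient of gold (Z = 79) near the Mn K-edge
# region, tabulated from the Henke/EPDL atomic scattering data as distributed
# by the xraylib compilation (CS_Total).  Units: energy_eV, mu_rho_cm2_g.
energy_eV	mu_rho_cm2_g
6400	361.6872
6425	358.1741
6450	354.7089
6475	351.2907
6500	347.9187
6525	344.5921
6550	341.3102
6575	338.0721
6600	334.8772
6625	331.7246
6650	328.6137
6675	325.5438
6700	322.5141
6725	319.5240
6750	316.5729
6775	313.6600
6800	310.7847
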