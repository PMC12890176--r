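{"N1_inf":1.22898171089613,"N2_inf":1.5,"M11_inf":1.01369298792919,"M12_inf":1.5,"M2_inf":0.245538409620756,"F_inf":1,"L21_inf":0.2,"L22_inf":1,"Deb_dam_inf":0.5,"Deb_H":0.5,"N_H":0.08,"M1_H":0.12,"gamma_n":0.010125248592237,"gamma_m":0.020912523588975,"gamma_l":0.02,"gamma_f":0.02,"omega_m2":0.3,"omega_f":0.563664430730161,"omega_dam":0.5,"kdn":0.004,"kdm1":0.002,"rho_dam":0.0085,"kdf":0.028,"kdnp":0.233365173589103,"kdm1p":0.288172471173266,"kdm2p":0.2,"ddeb":0.01,"snr":0.381493234142661,"dnr":0.1,"knd":0.176470891034142,"knp":0.1,"knn":0.02,"knm1p":0.301659850338474,"knm2p":0.4,"dn":0.0416844106344874,"smr":0.0666475835472299,"dmr_ud":0.0707529685770208,"dmr_d":0.015,"km1d":0.0574039045051066,"km1p":0.0911549818297475,"km1n":0.0673541992525421,"km1m1":0.02,"km1l1":0.02,"km2m1":0.0560008686821908,"km2m2":0.03,"km2l2":0.04,"theta_m1m2":0.5,"dm1":0.0782121045134263,"dm2":0.06,"slr":0.05,"dlr_ud":0.05,"dlr_d":0.05,"kl1":0.0360514970082482,"kl2":0.03,"dl":0.03,"sf":0.02,"ksttb_ud":0.005,"ksttb_d":0.004,"kf":0.01,"alpha_dam":0.013,"alpha_m2":0.05,"dfr_ud":0.015,"dfr_d":0.008,"df":0.02,"kpg":0.0455124907790422,"P_inf":1.09067452782155,"kpb":0.0743408925822796,"sb":1.2435561151084,"mu_b":1,"kbp":5.05630299573625,"kpn":0.172107520232443,"kpm1":0.15,"kpm2":0.15}
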