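# synthetic demonstration centroid panel (not a published PAM50 panel)
# 10 genes x 5 intrinsic subtypes; values are illustrative log2 centroids
# ror_coefficients: LuminalA=-0.34, LuminalB=0.23, HER2enriched=0.12, Basallike=0.05, Normallike=0.00
# ror_intercept: 50
# ror_scale: 100
gene	LuminalA	LuminalB	HER2enriched	Basallike	Normallike
PNL01	9.10	8.40	6.20	4.10	7.00
PNL02	8.70	8.90	5.80	4.50	6.90
PNL03	7.90	8.60	6.40	5.00	7.10
PNL04	5.20	6.10	9.30	6.80	6.50
PNL05	4.80	5.90	9.00	7.20	6.40
PNL06	4.20	5.10	6.90	9.40	6.20
PNL07	3.90	4.80	6.50	9.10	6.00
PNL08	6.50	7.20	7.00	8.60	6.80
PNL09	6.80	6.40	6.10	5.70	9.20
PNL10	7.10	6.60	6.30	5.40	8.90
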