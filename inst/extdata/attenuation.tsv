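# Linear attenuation coefficients (mm^-1) for the phantom and detector materials.
# mu_compton_mm: free-electron Klein-Nishina total cross-section times electron density.
# mu_photoelectric_mm: piecewise power law (local exponent 3.1 below 150 keV, 2.9 to 300 keV,
#   2.6 above) anchored at the photoelectric/Compton crossover (water 26 keV, Si 57 keV) and
#   at tau/rho = 1.30 cm^2/g for CdTe at 100 keV. No K-edge structure is modelled.
# Columns: material, energy_kev, mu_photoelectric_mm, mu_compton_mm
material	energy_kev	mu_photoelectric_mm	mu_compton_mm
water	20	0.0456486	0.0206581
water	25	0.0228563	0.0203078
water	30	0.0129881	0.019973
water	36	0.00738044	0.0195904
water	43	0.00425469	0.0191682
water	52	0.00236053	0.0186604
water	59.5	0.0015546	0.0182646
water	70	0.000939326	0.0177477
water	81	0.000597471	0.017248
water	100	0.0003109	0.0164716
water	120	0.000176668	0.0157537
water	140	0.000109553	0.0151193
water	171	6.04941e-05	0.0142685
water	200	3.84074e-05	0.0135879
water	240	2.26355e-05	0.0127893
water	280	1.44758e-05	0.0121151
water	330	9.24973e-06	0.0114035
water	390	5.99098e-06	0.0106924
water	460	3.90027e-06	0.0100059
water	511	2.96737e-06	0.00957846
water	560	2.33871e-06	0.00921295
water	600	1.95466e-06	0.00894191
silicon	20	0.989326	0.0432251
silicon	25	0.495357	0.0424922
silicon	30	0.281486	0.0417917
silicon	36	0.159954	0.040991
silicon	43	0.0922105	0.0401077
silicon	52	0.051159	0.0390452
silicon	59.5	0.0336922	0.0382169
silicon	70	0.0203577	0.0371354
silicon	81	0.0129488	0.0360899
silicon	100	0.00673802	0.0344653
silicon	120	0.00382887	0.0329631
silicon	140	0.0023743	0.0316358
silicon	171	0.00131107	0.0298554
silicon	200	0.000832391	0.0284314
silicon	240	0.000490571	0.0267604
silicon	280	0.00031373	0.0253498
silicon	330	0.000200466	0.0238608
silicon	390	0.00012984	0.0223728
silicon	460	8.45293e-05	0.0209364
silicon	511	6.43107e-05	0.020042
silicon	560	5.06861e-05	0.0192773
silicon	600	4.23628e-05	0.0187101
cadmium_telluride	20	111.662	0.0907143
cadmium_telluride	25	55.9094	0.0891762
cadmium_telluride	30	31.7704	0.0877061
cadmium_telluride	36	18.0535	0.0860258
cadmium_telluride	43	10.4075	0.084172
cadmium_telluride	52	5.77416	0.0819422
cadmium_telluride	59.5	3.80274	0.0802038
cadmium_telluride	70	2.29771	0.0779342
cadmium_telluride	81	1.46149	0.07574
cadmium_telluride	100	0.7605	0.0723306
cadmium_telluride	120	0.432153	0.069178
cadmium_telluride	140	0.26798	0.0663925
cadmium_telluride	171	0.147976	0.062656
cadmium_telluride	200	0.0939494	0.0596676
cadmium_telluride	240	0.0553692	0.0561607
cadmium_telluride	280	0.0354097	0.0532003
cadmium_telluride	330	0.022626	0.0500755
cadmium_telluride	390	0.0146547	0.0469527
cadmium_telluride	460	0.00954057	0.0439382
cadmium_telluride	511	0.00725856	0.0420612
cadmium_telluride	560	0.00572079	0.0404562
cadmium_telluride	600	0.00478136	0.039266
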