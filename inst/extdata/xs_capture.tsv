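symbol	sigma_thermal_b	E_gamma_MeV	Q_MeV
H	0.3326	2.2246	2.2246
C	0.0035	0	4.946
N	0.0750	0	10.833
O	0.00019	0	4.143
Na	0.530	0	6.959
Mg	0.063	0	7.331
Al	0.231	0	7.725
Si	0.171	0	8.476
P	0.172	0	7.935
S	0.530	0	8.640
Cl	33.50	0	8.580
Ar	0.675	0	6.100
K	2.100	0	7.800
Ca	0.430	0	8.363
Fe	2.560	0	7.646
I	6.150	0	6.826
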