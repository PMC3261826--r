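symbol	E_eV	sigma_b
H	1e-3	20.4
H	1e0	20.4
H	1e3	20.2
H	1e4	19.6
H	1e5	12.8
H	5e5	6.9
H	1e6	4.2
H	2e6	2.9
H	5e6	1.5
H	1e7	0.94
H	2e7	0.48
C	1e-3	4.95
C	1e0	4.74
C	1e4	4.7
C	1e5	4.5
C	1e6	2.6
C	2e6	1.7
C	5e6	1.2
C	1e7	1.0
C	2e7	0.9
N	1e-3	10.3
N	1e0	10.0
N	1e4	9.6
N	1e5	8.0
N	1e6	2.4
N	2e6	1.8
N	5e6	1.2
N	2e7	0.9
O	1e-3	3.9
O	1e0	3.9
O	1e4	3.8
O	1e5	3.5
O	1e6	3.2
O	2e6	1.8
O	5e6	1.1
O	8e6	0.9
O	2e7	0.7
Na	1e-3	3.4
Na	1e0	3.3
Na	1e5	3.5
Na	1e6	2.8
Na	2e7	0.9
Mg	1e-3	3.5
Mg	1e0	3.4
Mg	1e5	3.6
Mg	1e6	2.6
Mg	2e7	0.9
Al	1e-3	1.5
Al	1e0	1.41
Al	1e5	2.8
Al	1e6	2.4
Al	5e6	1.6
Al	2e7	1.0
Si	1e-3	2.1
Si	1e0	2.0
Si	1e5	2.6
Si	1e6	2.8
Si	5e6	1.8
Si	2e7	1.0
P	1e-3	3.2
P	1e0	3.1
P	1e5	3.3
P	1e6	2.8
P	2e7	1.0
S	1e-3	1.0
S	1e0	0.98
S	1e5	2.2
S	1e6	2.6
S	2e7	1.0
Cl	1e-3	16.0
Cl	1e0	15.8
Cl	1e5	6.0
Cl	1e6	2.8
Cl	2e7	1.0
Ar	1e-3	0.68
Ar	1e0	0.66
Ar	1e5	1.5
Ar	1e6	2.5
Ar	2e7	1.0
K	1e-3	2.2
K	1e0	2.1
K	1e5	2.8
K	1e6	2.9
K	2e7	1.0
Ca	1e-3	3.0
Ca	1e0	2.9
Ca	1e5	2.8
Ca	1e6	2.5
Ca	2e7	1.1
Fe	1e-3	11.6
Fe	1e0	11.3
Fe	1e5	6.0
Fe	1e6	3.0
Fe	2e7	1.2
I	1e-3	3.7
I	1e0	3.6
I	1e5	5.0
I	1e6	5.5
I	2e7	2.0
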