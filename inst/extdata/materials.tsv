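id	name	density_g_cm3	state	comp_type	tissue	composition
0	vacuum	0	gas	atom	0	H:1
1	water	1.000	solid	atom	0	H:2;O:1
2	perspex	1.19	solid	atom	0	C:5;O:2;H:8
3	aluminum	2.699	solid	atom	0	Al:1
4	concrete	2.300	solid	mass	0	H:0.010;C:0.001;O:0.529107;Na:0.016;Mg:0.002;Al:0.033872;Si:0.337021;K:0.013;Ca:0.044;Fe:0.014
5	air	0.0012048	gas	mass	0	C:0.000124;N:0.755268;O:0.231781;Ar:0.012827
11	brain	1.04	solid	mass	1	H:0.107;C:0.145;N:0.022;O:0.712;Na:0.002;P:0.004;S:0.002;Cl:0.003;K:0.003
12	blood	1.06	solid	mass	1	H:0.102;C:0.110;N:0.033;O:0.745;Na:0.001;P:0.001;S:0.002;Cl:0.003;K:0.002;Fe:0.001
13	bone_cortical	1.92	solid	mass	1	H:0.035;C:0.160;N:0.042;O:0.445;Na:0.003;Mg:0.002;P:0.095;S:0.003;Ca:0.215
14	spongiosa	1.18	solid	mass	1	H:0.085;C:0.404;N:0.028;O:0.367;Na:0.002;Mg:0.002;P:0.034;S:0.002;Cl:0.002;K:0.001;Ca:0.073
15	marrow_red	1.03	solid	mass	1	H:0.105;C:0.414;N:0.034;O:0.439;P:0.001;S:0.002;Cl:0.002;K:0.002;Fe:0.001
16	marrow_yellow	0.98	solid	mass	1	H:0.115;C:0.644;N:0.007;O:0.231;Na:0.001;S:0.001;Cl:0.001
17	cartilage	1.10	solid	mass	1	H:0.096;C:0.099;N:0.022;O:0.744;Na:0.005;P:0.022;S:0.009;Cl:0.003
18	eye_lens	1.07	solid	mass	1	H:0.096;C:0.195;N:0.057;O:0.646;Na:0.001;P:0.001;S:0.003;Cl:0.001
19	skin	1.09	solid	mass	1	H:0.100;C:0.204;N:0.042;O:0.645;Na:0.002;P:0.001;S:0.002;Cl:0.003;K:0.001
20	soft_tissue	1.05	solid	mass	1	H:0.105;C:0.256;N:0.027;O:0.602;Na:0.001;P:0.002;S:0.003;Cl:0.002;K:0.002
21	muscle	1.05	solid	mass	1	H:0.102;C:0.143;N:0.034;O:0.710;Na:0.001;P:0.002;S:0.003;Cl:0.001;K:0.004
22	salivary_gland	1.03	solid	mass	1	H:0.105;C:0.114;N:0.027;O:0.745;Na:0.002;P:0.002;S:0.003;Cl:0.001;K:0.001
23	thyroid	1.05	solid	mass	1	H:0.104;C:0.119;N:0.024;O:0.745;Na:0.002;P:0.001;S:0.001;Cl:0.002;K:0.001;I:0.001
24	lung_deflated	1.05	solid	mass	1	H:0.103;C:0.105;N:0.031;O:0.749;Na:0.002;P:0.002;S:0.003;Cl:0.003;K:0.002
25	lung_inflated	0.26	solid	mass	1	H:0.103;C:0.105;N:0.031;O:0.749;Na:0.002;P:0.002;S:0.003;Cl:0.003;K:0.002
26	teeth	2.75	solid	mass	1	H:0.022;C:0.095;N:0.029;O:0.421;Mg:0.007;P:0.137;Ca:0.289
27	breast	1.02	solid	mass	1	H:0.106;C:0.332;N:0.030;O:0.527;Na:0.001;P:0.001;S:0.002;Cl:0.001
28	adipose	0.95	solid	mass	1	H:0.114;C:0.598;N:0.007;O:0.278;Na:0.001;S:0.001;Cl:0.001
29	liver	1.06	solid	mass	1	H:0.102;C:0.139;N:0.030;O:0.716;Na:0.002;P:0.003;S:0.003;Cl:0.002;K:0.003
30	kidney	1.05	solid	mass	1	H:0.103;C:0.132;N:0.030;O:0.724;Na:0.002;P:0.002;S:0.002;Cl:0.002;K:0.002;Ca:0.001
31	spleen	1.06	solid	mass	1	H:0.103;C:0.113;N:0.032;O:0.741;Na:0.001;P:0.003;S:0.002;Cl:0.002;K:0.003
32	gi_tract	1.03	solid	mass	1	H:0.106;C:0.115;N:0.022;O:0.751;Na:0.001;P:0.001;S:0.001;Cl:0.002;K:0.001
33	pancreas	1.04	solid	mass	1	H:0.106;C:0.169;N:0.022;O:0.694;Na:0.002;P:0.002;S:0.001;Cl:0.002;K:0.002
34	heart	1.05	solid	mass	1	H:0.104;C:0.139;N:0.029;O:0.718;Na:0.001;P:0.002;S:0.002;Cl:0.002;K:0.003
35	thymus	1.03	solid	mass	1	H:0.105;C:0.120;N:0.027;O:0.738;Na:0.002;P:0.003;S:0.002;Cl:0.002;K:0.001
36	bladder	1.04	solid	mass	1	H:0.105;C:0.096;N:0.026;O:0.761;Na:0.002;P:0.002;S:0.002;Cl:0.003;K:0.003
37	gonads	1.04	solid	mass	1	H:0.105;C:0.093;N:0.024;O:0.766;Na:0.002;P:0.002;S:0.002;Cl:0.002;K:0.002;Ca:0.002
38	spinal_cord	1.04	solid	mass	1	H:0.107;C:0.144;N:0.022;O:0.712;Na:0.002;P:0.005;S:0.002;Cl:0.003;K:0.003
39	mucosa	1.05	solid	mass	1	H:0.106;C:0.097;N:0.022;O:0.761;Na:0.002;P:0.002;S:0.002;Cl:0.003;K:0.005
40	tongue	1.05	solid	mass	1	H:0.102;C:0.144;N:0.034;O:0.708;Na:0.001;P:0.002;S:0.003;Cl:0.002;K:0.004
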