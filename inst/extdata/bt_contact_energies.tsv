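	C	M	F	I	L	V	W	Y	A	G	T	S	N	Q	D	E	H	R	K	P
C	-1.34	-0.49	-0.53	-0.48	-0.50	-0.51	-0.74	-0.16	-0.26	-0.09	0.00	0.09	0.28	0.04	0.38	0.46	-0.19	0.32	0.35	-0.18
M	-0.49	-0.56	-0.89	-0.60	-0.68	-0.47	-0.94	-0.51	-0.23	0.08	0.00	0.32	0.32	-0.01	0.62	0.24	-0.17	0.17	0.22	-0.16
F	-0.53	-0.89	-0.82	-0.65	-0.78	-0.67	-0.78	-0.49	-0.33	0.11	0.00	0.10	0.29	-0.04	0.48	0.34	-0.19	0.08	0.11	-0.19
I	-0.48	-0.60	-0.65	-0.60	-0.79	-0.68	-0.65	-0.33	-0.35	0.21	0.00	0.35	0.55	0.14	0.54	0.38	0.19	0.18	0.21	0.05
L	-0.50	-0.68	-0.78	-0.79	-0.81	-0.80	-0.70	-0.44	-0.37	0.14	0.00	0.26	0.36	0.08	0.62	0.37	0.10	0.09	0.16	-0.08
V	-0.51	-0.47	-0.67	-0.68	-0.80	-0.72	-0.62	-0.27	-0.38	0.04	0.00	0.25	0.39	0.17	0.66	0.41	0.18	0.17	0.16	-0.08
W	-0.74	-0.94	-0.78	-0.65	-0.70	-0.62	-0.74	-0.55	-0.40	-0.24	0.00	0.07	-0.09	-0.11	0.06	-0.15	-0.46	-0.41	-0.28	-0.73
Y	-0.16	-0.51	-0.49	-0.33	-0.44	-0.27	-0.55	-0.27	-0.15	-0.04	0.00	0.07	0.01	-0.18	-0.07	-0.16	-0.21	-0.37	-0.40	-0.40
A	-0.26	-0.23	-0.33	-0.35	-0.37	-0.38	-0.40	-0.15	-0.20	-0.03	0.00	0.15	0.24	0.21	0.30	0.43	0.21	0.27	0.20	0.07
G	-0.09	0.08	0.11	0.21	0.14	0.04	-0.24	-0.04	-0.03	-0.20	0.00	0.10	0.10	0.20	0.17	0.48	0.23	0.14	0.12	-0.01
T	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00	0.00
S	0.09	0.32	0.10	0.35	0.26	0.25	0.07	0.07	0.15	0.10	0.00	0.13	0.14	0.25	0.01	0.10	0.15	0.12	0.10	0.17
N	0.28	0.32	0.29	0.55	0.36	0.39	-0.09	0.01	0.24	0.10	0.00	0.14	-0.04	-0.05	-0.12	-0.01	0.10	0.02	-0.14	0.13
Q	0.04	-0.01	-0.04	0.14	0.08	0.17	-0.11	-0.18	0.21	0.20	0.00	0.25	-0.05	0.14	0.12	0.10	0.22	-0.12	-0.20	-0.05
D	0.38	0.62	0.48	0.54	0.62	0.66	0.06	-0.07	0.30	0.17	0.00	0.01	-0.12	0.12	0.27	0.40	-0.22	-0.71	-0.69	0.25
E	0.46	0.24	0.34	0.38	0.37	0.41	-0.15	-0.16	0.43	0.48	0.00	0.10	-0.01	0.10	0.40	0.45	-0.11	-0.75	-0.87	0.26
H	-0.19	-0.17	-0.19	0.19	0.10	0.18	-0.46	-0.21	0.21	0.23	0.00	0.15	0.10	0.22	-0.22	-0.11	-0.33	0.04	0.26	-0.05
R	0.32	0.17	0.08	0.18	0.09	0.17	-0.41	-0.37	0.27	0.14	0.00	0.12	0.02	-0.12	-0.71	-0.75	0.04	0.13	0.50	-0.02
K	0.35	0.22	0.11	0.21	0.16	0.16	-0.28	-0.40	0.20	0.12	0.00	0.10	-0.14	-0.20	-0.69	-0.87	0.26	0.50	0.38	0.12
P	-0.18	-0.16	-0.19	0.05	-0.08	-0.08	-0.73	-0.40	0.07	-0.01	0.00	0.17	0.13	-0.05	0.25	0.26	-0.05	-0.02	0.12	-0.07
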