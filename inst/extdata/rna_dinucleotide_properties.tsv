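property	AA	AC	AG	AU	CA	CC	CG	CU	GA	GC	GG	GU	UA	UC	UG	UU
Rise (RNA)	3.18	3.24	3.30	3.24	3.09	3.32	3.30	3.30	3.38	3.22	3.32	3.24	3.26	3.38	3.09	3.18
Roll (RNA)	7.0	4.8	8.5	7.1	9.9	8.7	12.1	8.5	9.4	6.1	8.7	4.8	10.7	9.4	9.9	7.0
Shift (RNA)	-0.08	0.23	-0.04	-0.06	0.11	-0.01	0.30	-0.04	0.07	0.07	-0.01	0.23	-0.02	0.07	0.11	-0.08
Slide (RNA)	-1.27	-1.43	-1.50	-1.36	-1.46	-1.78	-1.89	-1.50	-1.70	-1.39	-1.78	-1.43	-1.45	-1.70	-1.46	-1.27
Tilt (RNA)	-0.8	0.8	0.5	1.1	1.0	0.3	-0.1	0.5	1.3	0.0	0.3	0.8	-0.2	1.3	1.0	-0.8
Twist (RNA)	31	32	30	33	31	32	27	30	32	35	32	32	32	32	31	31
Entropy (RNA)	-18.4	-26.2	-19.2	-15.5	-27.8	-29.7	-19.4	-19.2	-35.5	-34.9	-29.7	-26.2	-23.6	-35.5	-27.8	-18.4
Adenine content	2	1	1	1	1	0	0	0	1	0	0	0	1	0	0	0
Purine (AG) content	2	1	2	1	1	0	1	0	2	1	2	1	1	0	1	0
Hydrophilicity (RNA)	0.023	0.083	0.035	0.090	0.118	0.349	0.193	0.378	0.048	0.146	0.065	0.160	0.112	0.359	0.224	0.389
Enthalpy (RNA)1	-6.6	-10.2	-7.6	-5.7	-10.5	-12.2	-8.0	-7.6	-13.3	-14.2	-12.2	-10.2	-8.1	-10.2	-7.6	-6.6
GC content	0	1	1	0	1	2	2	1	1	2	2	1	0	1	1	0
Entropy (RNA)1	-21.9	-23.5	-21.0	-16.8	-22.9	-28.4	-16.2	-21.0	-33.0	-34.0	-28.4	-23.5	-20.5	-33.0	-22.9	-21.9
Hydrophilicity (RNA)1	0.04	0.14	0.08	0.12	0.21	0.49	0.35	0.52	0.10	0.26	0.17	0.27	0.21	0.48	0.34	0.44
Free energy (RNA)	-0.93	-2.24	-2.08	-1.10	-2.11	-3.26	-2.36	-2.08	-2.35	-3.42	-3.26	-2.24	-1.33	-2.35	-2.11	-0.93
Keto (GT) content	0	0	1	1	0	0	1	1	1	1	2	2	1	1	2	2
Free energy (RNA)1	-0.9	-1.8	-2.3	-1.1	-1.7	-2.9	-2.1	-1.8	-2.3	-3.4	-2.9	-2.3	-0.9	-2.1	-1.9	-0.9
Enthalpy (RNA)	-6.82	-11.40	-10.48	-9.38	-10.44	-13.39	-10.64	-10.48	-12.44	-14.88	-13.39	-11.40	-7.69	-12.44	-10.44	-6.82
Stacking energy (RNA)	-13.7	-13.8	-14.0	-15.4	-14.4	-11.1	-15.6	-14.0	-14.2	-16.9	-11.1	-13.8	-16.0	-14.2	-14.4	-13.7
Guanine content	0	0	1	0	0	0	1	0	1	1	2	1	0	0	1	0
Cytosine content	0	1	0	0	1	2	1	1	0	1	0	0	0	1	0	0
Thymine content	0	0	0	1	0	0	0	1	0	0	0	1	1	1	1	2
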