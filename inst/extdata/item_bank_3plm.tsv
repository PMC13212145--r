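icf_code	label	a	b	g	b_mc	bi_norm	bi_significant	impaired_example	main_component
d430	Lifting and carrying objects	5.59	1.04	0	1.03	1	1	1	1
d475	Driving	1.99	0.98	0	0.96	0.51	1	1	1
b730	Muscle power functions	2.14	0.91	0	0.90	0.64	1	1	1
b4552	Fatigability	2.84	0.89	0	0.88	0.72	1	1	1
b130	Energy and drive functions	2.56	0.80	3e-04	0.79	0.57	1	1	1
d240	Handling stress and other psychological demands	1.77	0.74	1e-04	0.74	0.60	1	1	1
b535	Sensations associated with the digestive system	2.35	0.58	0.10	0.57	0.42	1	1	1
d460	Moving around in different locations	4.26	0.35	0	0.35	0.80	1	1	1
b250	Taste function	59.49	0.30	0.32	0.29	0.69	1	1	0
b1563	Gustatory perception	59.53	0.30	0.32	0.29	0.65	1	1	0
b126	Temperament and personality functions	2.21	0.16	0.04	0.16	0.46	1	1	1
b144	Memory functions	0.85	0.08	1e-04	0.15	0.38	1	1	1
d5701	Managing diet and fitness	2.41	-0.03	0	-0.02	0.18	1	1	1
d520	Caring for body parts	5.74	-0.05	0	-0.04	0.61	1	1	1
d510	Washing oneself	6.91	-0.05	0	-0.04	0.60	1	1	1
b164	Higher-level cognitive functions	1.59	-0.10	9e-04	-0.07	0.24	1	0	1
d470	Using transportation	3.49	-0.13	0.01	-0.13	0.26	1	1	1
b530	Weight maintenance functions	2.71	-0.17	0.06	-0.17	0.04	0	1	1
b280	Sensation of pain	1.25	-0.22	0.15	-0.22	0.35	1	1	0
d435	Moving objects with lower extremities	2.38	-0.27	0	-0.25	0.40	1	1	1
d455	Moving around	4.23	-0.30	0	-0.29	0.37	1	0	1
b510	Ingestion functions	3.02	-0.33	0.34	-0.32	0.15	1	0	1
b545	Water, mineral, and electrolyte balance functions	0.99	-0.47	4e-04	-0.38	0.28	1	0	1
b515	Digestive functions	1.43	-0.44	0.12	-0.43	0.23	1	0	0
d530	Toileting	5.65	-0.60	0.09	-0.59	0.15	1	0	1
d450	Walking	3.51	-0.61	0.02	-0.60	0.27	1	0	1
d420	Transferring oneself	4.44	-0.92	1e-04	-0.90	0.07	0	0	1
b520	Assimilation functions	1.18	-1.00	8e-04	-0.90	0.25	1	1	0
b152	Emotional functions	1.32	-1.04	1e-04	-0.96	0.08	0	1	1
d410	Changing basic body position	4.68	-1.06	0	-1.05	0.13	1	0	1
d465	Moving around using equipment	1.78	-1.12	1e-04	-1.07	0.09	0	1	1
d415	Maintaining a body position	4.41	-1.11	1e-04	-1.09	0.06	0	0	1
b160	Thought functions	2.31	-1.17	1e-04	-1.12	0.11	1	0	1
d540	Dressing	2.43	-1.21	2e-04	-1.17	0.08	0	1	1
b140	Attention functions	1.63	-1.45	0.01	-1.37	0.09	0	0	1
b4152	Functions of veins	1.77	-1.61	6e-04	-1.53	0.08	0	0	0
d440	Fine hand use	3.41	-1.66	1e-04	-1.65	0.08	0	0	0
d445	Hand and arm use	3.76	-1.67	1e-04	-1.65	0.06	0	0	0
b117	Intellectual functions	1.88	-2.03	2e-04	-1.92	0.05	0	0	1
b810	Protective functions of the skin	1.18	-2.23	3e-04	-2.00	0.21	1	0	0
b820	Repair functions of the skin	1.10	-2.28	3e-04	-2.01	0.21	1	0	0
d550	Eating	1.60	-2.46	3e-04	-2.30	0.06	0	0	1
d560	Drinking	1.97	-2.44	3e-04	-2.32	-0.01	0	0	1
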