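response	measure	n_obs	intercept	b_mean_individual_clutch	has_population	has_sex	df	logLik	AICc	delta	weight
timescale	absolute	787	0.25	NA	0	0	2	-539.26	1082.50	0.00	0.23
timescale	absolute	787	0.36	NA	1	0	5	-536.49	1083.10	0.52	0.18
timescale	absolute	787	0.40	-0.17	1	0	6	-535.67	1083.40	0.90	0.15
timescale	absolute	787	0.25	0.07	0	0	3	-538.75	1083.50	0.98	0.14
timescale	absolute	787	0.28	NA	0	1	3	-539.15	1084.30	1.78	0.10
timescale	absolute	787	0.40	NA	1	1	6	-536.35	1084.80	2.26	0.08
timescale	absolute	787	0.44	-0.17	1	1	7	-535.54	1085.20	2.68	0.06
timescale	absolute	787	0.29	0.07	0	1	4	-538.62	1085.30	2.76	0.06
timescale	centred	846	0.39	NA	0	1	3	-576.50	1159.00	0.00	0.29
timescale	centred	846	0.39	0.09	0	1	4	-575.75	1159.50	0.51	0.22
timescale	centred	846	0.28	NA	0	0	2	-578.15	1160.30	1.28	0.15
timescale	centred	846	0.67	NA	1	1	6	-574.38	1160.90	1.84	0.11
timescale	centred	846	0.28	0.08	0	0	3	-577.45	1160.90	1.90	0.11
timescale	centred	846	0.54	NA	1	0	5	-576.19	1162.40	3.43	0.05
timescale	centred	846	0.67	0.04	1	1	7	-574.33	1162.80	3.76	0.04
timescale	centred	846	0.53	0.03	1	0	6	-576.15	1164.40	5.38	0.02
amplitude_short	absolute	633	-0.88	0.06	0	1	5	-564.37	1138.80	0.00	0.46
amplitude_short	absolute	633	-0.81	NA	1	1	7	-562.73	1139.60	0.80	0.31
amplitude_short	absolute	633	-0.82	0.04	1	1	8	-562.34	1140.90	2.07	0.16
amplitude_short	absolute	633	-0.88	NA	0	1	4	-567.47	1143.00	4.17	0.06
amplitude_short	absolute	633	-0.81	0.06	0	0	4	-569.73	1147.50	8.69	0.01
amplitude_short	absolute	633	-0.74	NA	1	0	6	-568.28	1148.70	9.87	0.00
amplitude_short	absolute	633	-0.75	0.04	1	0	7	-567.85	1149.90	11.05	0.00
amplitude_short	absolute	633	-0.81	NA	0	0	3	-572.80	1151.60	12.81	0.00
amplitude_short	centred	779	0.56	NA	0	1	4	-47.32	102.70	0.00	0.61
amplitude_short	centred	779	0.56	0.01	0	1	5	-47.03	104.10	1.44	0.30
amplitude_short	centred	779	0.57	NA	1	1	7	-46.54	107.20	4.54	0.06
amplitude_short	centred	779	0.57	0.00	1	1	8	-46.53	109.30	6.57	0.02
amplitude_short	centred	779	0.58	NA	0	0	3	-53.08	112.20	9.50	0.01
amplitude_short	centred	779	0.59	0.01	0	0	4	-52.75	113.60	10.86	0.00
amplitude_short	centred	779	0.60	NA	1	0	6	-52.35	116.80	14.11	0.00
amplitude_short	centred	779	0.60	0.00	1	0	7	-52.32	118.80	16.10	0.00
amplitude_long	absolute	633	-0.93	NA	1	1	7	-563.69	1141.50	0.00	0.54
amplitude_long	absolute	633	-0.94	0.02	1	1	8	-563.62	1143.50	1.92	0.21
amplitude_long	absolute	633	-0.97	0.10	0	1	5	-567.01	1144.10	2.56	0.15
amplitude_long	absolute	633	-0.88	NA	1	0	6	-566.86	1145.80	4.29	0.06
amplitude_long	absolute	633	-0.88	0.02	1	0	7	-566.77	1147.70	6.17	0.02
amplitude_long	absolute	633	-0.91	0.10	0	0	4	-569.87	1147.80	6.26	0.02
amplitude_long	absolute	633	-0.97	NA	0	1	4	-576.16	1160.40	18.83	0.00
amplitude_long	absolute	633	-0.91	NA	0	0	3	-578.94	1163.90	22.38	0.00
amplitude_long	centred	779	0.63	NA	1	1	7	114.53	-214.90	0.00	0.72
amplitude_long	centred	779	0.63	0.00	1	1	8	114.53	-212.90	2.04	0.26
amplitude_long	centred	779	0.60	0.03	0	1	5	108.78	-207.50	7.43	0.02
amplitude_long	centred	779	0.66	NA	1	0	6	106.90	-201.70	13.22	0.00
amplitude_long	centred	779	0.66	0.00	1	0	7	106.93	-199.70	15.20	0.00
amplitude_long	centred	779	0.60	NA	0	1	4	103.31	-198.60	16.35	0.00
amplitude_long	centred	779	0.62	0.03	0	0	4	101.60	-195.10	19.77	0.00
amplitude_long	centred	779	0.62	NA	0	0	3	95.93	-185.80	29.08	0.00
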