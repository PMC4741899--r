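upn	cohort	agvhd_grade	total_printed	note	R_A_1	R_A_2	R_B_1	R_B_2	R_DRB1_1	R_DRB1_2	R_DQB1_1	R_DQB1_2	D_A_1	D_A_2	D_B_1	D_B_2	D_DRB1_1	D_DRB1_2	D_DQB1_1	D_DQB1_2
R-UPN01	retrospective	I	0.2958		A*02:01	A*11:01	B*13:01	B*40:01	DRB1*12:01	DRB1*15:01	DQB1*03:01	DQB1*06:01	A*02:01	A*33:01	B*40:01	B*44:02	DRB1*12:01	DRB1*13:01	DQB1*03:01	DQB1*06:01
R-UPN02	retrospective	III	0.9975		A*11:01	A*24:02	B*15:01	B*40:01	DRB1*11:01	DRB1*15:01	DQB1*03:01	DQB1*05:01	A*11:01	A*11:01	B*15:01	B*46:01	DRB1*12:01	DRB1*15:01	DQB1*03:01	DQB1*05:01
R-UPN03	retrospective	II	0.3755		A*02:01	A*11:01	B*40:01	B*40:01	DRB1*09:01	DRB1*11:01	DQB1*03:01	DQB1*03:03	A*11:01	A*11:01	B*40:01	B*46:01	DRB1*09:01	DRB1*11:01	DQB1*03:01	DQB1*03:03
R-UPN04	retrospective	II	0.3807		A*01:01	A*02:01	B*13:01	B*37:01	DRB1*10:01	DRB1*16:01	DQB1*05:01	DQB1*05:01	A*01:01	A*33:01	B*13:01	B*37:01	DRB1*10:01	DRB1*16:01	DQB1*05:01	DQB1*05:01
R-UPN05	retrospective	II	0.3680	total_printed_0.368	A*11:01	A*30:01	B*13:01	B*15:01	DRB1*13:01	DRB1*13:01	DQB1*06:01	DQB1*06:01	A*11:01	A*30:01	B*13:01	B*44:02	DRB1*04:06	DRB1*13:01	DQB1*03:02	DQB1*06:01
R-UPN06	retrospective	II	0.0838		A*02:01	A*33:01	B*07:02	B*40:01	DRB1*04:01	DRB1*04:01	DQB1*02:01	DQB1*03:01	A*02:01	A*33:01	B*07:02	B*40:01	DRB1*04:04	DRB1*04:04	DQB1*02:01	DQB1*03:01
R-UPN07	retrospective	IV	0.4317	hla_ab_recombination	A*02:01	A*02:03	B*38:01	B*52:01	DRB1*04:01	DRB1*07:01	DQB1*02:01	DQB1*04:01	A*02:03	A*68:01	B*38:01	B*52:01	DRB1*04:01	DRB1*07:01	DQB1*02:01	DQB1*04:01
R-UPN08	retrospective	IV	0.6474		A*02:01	A*30:01	B*38:01	B*40:01	DRB1*11:01	DRB1*15:01	DQB1*03:01	DQB1*06:01	A*02:01	A*30:01	B*39:02	B*40:01	DRB1*11:01	DRB1*15:01	DQB1*03:01	DQB1*06:04
R-UPN09	retrospective	II	0.3750		A*02:01	A*24:02	B*35:01	B*40:02	DRB1*08:01	DRB1*15:01	DQB1*06:01	DQB1*06:01	A*02:01	A*02:01	B*35:01	B*40:02	DRB1*15:01	DRB1*16:01	DQB1*05:01	DQB1*06:01
R-UPN10	retrospective	IV	0.6333		A*02:01	A*11:01	B*07:02	B*15:01	DRB1*01:01	DRB1*15:01	DQB1*03:11	DQB1*05:01	A*02:01	A*11:01	B*07:02	B*15:01	DRB1*01:01	DRB1*15:01	DQB1*05:01	DQB1*06:11
R-UPN11	retrospective	IV	0.5059		A*11:01	A*33:01	B*40:02	B*58:01	DRB1*12:01	DRB1*16:01	DQB1*03:01	DQB1*05:01	A*11:01	A*33:01	B*13:01	B*58:01	DRB1*12:01	DRB1*16:05	DQB1*03:04	DQB1*05:01
R-UPN12	retrospective	I	0.2211		A*02:01	A*30:01	B*13:01	B*55:01	DRB1*07:01	DRB1*12:01	DQB1*02:01	DQB1*03:01	A*02:01	A*30:01	B*13:01	B*55:01	DRB1*07:01	DRB1*11:01	DQB1*02:01	DQB1*03:02
P-UPN01	prospective	IV	1.4094		A*11:01	A*31:01	B*46:01	B*48:01	DRB1*08:01	DRB1*14:01	DQB1*05:01	DQB1*06:01	A*02:07	A*11:01	B*46:01	B*51:01	DRB1*08:01	DRB1*12:01	DQB1*03:01	DQB1*06:01
P-UPN02	prospective	II	0.1363		A*24:02	A*33:01	B*35:01	B*55:01	DRB1*04:01	DRB1*12:01	DQB1*02:01	DQB1*05:01	A*02:07	A*33:01	B*35:01	B*55:01	DRB1*04:01	DRB1*12:01	DQB1*02:01	DQB1*05:01
P-UPN03	prospective	I	0.2579	panel_total_0.2580	A*24:02	A*33:01	B*15:01	B*44:03	DRB1*11:01	DRB1*14:01	DQB1*03:01	DQB1*06:01	A*11:01	A*24:02	B*15:01	B*44:02	DRB1*04:01	DRB1*11:01	DQB1*03:01	DQB1*06:01
P-UPN04	prospective	II	0.3976	total_discrepant_components_sum_0.4576	A*02:01	A*33:01	B*40:01	B*51:01	DRB1*04:01	DRB1*15:01	DQB1*03:02	DQB1*06:01	A*02:01	A*03:01	B*35:01	B*40:01	DRB1*04:01	DRB1*15:01	DQB1*03:02	DQB1*06:01
P-UPN05	prospective	II	0.3976	total_discrepant_components_sum_0.3808	A*02:01	A*31:01	B*46:01	B*51:01	DRB1*12:01	DRB1*15:02	DQB1*03:01	DQB1*05:01	A*02:01	A*31:01	B*38:02	B*51:01	DRB1*12:01	DRB1*16:02	DQB1*03:01	DQB1*05:01
P-UPN06	prospective	I	0.1832		A*11:01	A*11:01	B*18:01	B*40:01	DRB1*09:01	DRB1*14:01	DQB1*03:02	DQB1*04:01	A*11:01	A*24:02	B*35:01	B*40:01	DRB1*04:01	DRB1*09:01	DQB1*03:02	DQB1*04:01
P-UPN07	prospective	I	0.1102		A*02:01	A*02:01	B*13:01	B*40:06	DRB1*08:03	DRB1*12:02	DQB1*03:01	DQB1*05:01	A*02:01	A*02:03	B*13:01	B*40:01	DRB1*08:03	DRB1*12:02	DQB1*03:01	DQB1*05:01
P-UPN08	prospective			not_transplanted	A*11:01	A*30:01	B*13:01	B*38:01	DRB1*07:01	DRB1*12:02	DQB1*02:01	DQB1*03:01								
P-UPN09	prospective			not_transplanted	A*02:03	A*11:01	B*38:02	B*40:01	DRB1*04:06	DRB1*15:02	DQB1*03:01	DQB1*06:01								
P-UPN10	prospective	II	0.4472		A*02:01	A*24:02	B*27:07	B*44:02	DRB1*01:01	DRB1*11:01	DQB1*03:01	DQB1*05:01	A*02:01	A*02:05	B*44:02	B*44:02	DRB1*01:01	DRB1*11:01	DQB1*03:01	DQB1*05:01
P-UPN11	prospective	IV	0.7544		A*02:01	A*11:01	B*13:01	B*15:01	DRB1*11:01	DRB1*11:01	DQB1*03:01	DQB1*03:01	A*11:01	A*30:01	B*13:01	B*13:02	DRB1*11:01	DRB1*11:01	DQB1*03:01	DQB1*03:01
P-UPN12	prospective	II	0.3755		A*11:01	A*24:02	B*40:01	B*51:01	DRB1*04:04	DRB1*15:01	DQB1*03:02	DQB1*06:01	A*02:01	A*24:02	B*40:01	B*51:01	DRB1*04:04	DRB1*15:01	DQB1*03:02	DQB1*06:01
P-UPN13	prospective	IV	1.2944		A*02:01	A*26:01	B*15:01	B*51:01	DRB1*09:01	DRB1*13:01	DQB1*03:03	DQB1*06:01	A*02:01	A*30:01	B*13:01	B*15:01	DRB1*07:01	DRB1*09:01	DQB1*02:01	DQB1*03:03
P-UPN14	prospective	I	0.0403		A*01:01	A*11:01	B*37:01	B*54:01	DRB1*08:01	DRB1*10:01	DQB1*05:01	DQB1*06:01	A*01:01	A*26:01	B*37:01	B*54:01	DRB1*08:01	DRB1*10:01	DQB1*05:01	DQB1*06:01
P-UPN15	prospective	III	0.8127		A*11:01	A*24:02	B*37:01	B*40:01	DRB1*04:01	DRB1*10:01	DQB1*02:01	DQB1*05:01	A*11:01	A*24:02	B*40:01	B*46:01	DRB1*04:01	DRB1*09:01	DQB1*02:01	DQB1*05:01
P-UPN16	prospective	I	0.2595		A*02:01	A*02:01	B*40:01	B*54:01	DRB1*08:01	DRB1*11:01	DQB1*03:01	DQB1*06:01	A*02:01	A*02:01	B*40:01	B*46:01	DRB1*08:01	DRB1*11:01	DQB1*03:01	DQB1*06:01
P-UPN17	prospective	III	0.7682		A*11:01	A*31:01	B*35:01	B*40:02	DRB1*11:01	DRB1*13:01	DQB1*03:01	DQB1*03:01	A*02:01	A*31:01	B*13:01	B*40:02	DRB1*11:01	DRB1*13:01	DQB1*03:01	DQB1*06:01
P-UPN18	prospective	IV	0.5978		A*11:01	A*11:03	B*15:18	B*35:01	DRB1*03:01	DRB1*15:01	DQB1*02:01	DQB1*06:01	A*01:01	A*11:01	B*35:01	B*57:01	DRB1*07:01	DRB1*15:01	DQB1*02:01	DQB1*06:01
P-UPN19	prospective	IV	0.8322		A*02:01	A*02:01	B*13:01	B*46:01	DRB1*04:01	DRB1*09:01	DQB1*03:02	DQB1*03:03	A*02:01	A*02:01	B*13:01	B*46:01	DRB1*04:01	DRB1*15:01	DQB1*03:02	DQB1*05:01
P-UPN20	prospective	IV	0.7627		A*30:01	A*31:01	B*35:01	B*40:06	DRB1*09:01	DRB1*12:01	DQB1*03:01	DQB1*03:03	A*24:02	A*30:01	B*35:01	B*51:01	DRB1*09:01	DRB1*12:01	DQB1*03:01	DQB1*03:03
P-UPN21	prospective	II	0.1472		A*02:01	A*24:02	B*39:01	B*46:01	DRB1*09:01	DRB1*12:01	DQB1*03:01	DQB1*03:03	A*02:01	A*02:01	B*39:01	B*46:01	DRB1*09:01	DRB1*12:01	DQB1*03:01	DQB1*03:03
P-UPN22	prospective	III	0.6499		A*02:01	A*02:01	B*07:05	B*27:07	DRB1*03:01	DRB1*15:01	DQB1*02:01	DQB1*06:01	A*02:01	A*30:01	B*13:01	B*27:07	DRB1*03:01	DRB1*07:01	DQB1*02:01	DQB1*06:01
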