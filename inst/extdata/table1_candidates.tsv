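accession	protein_id	mw_kda	rho_pnd4	p_pnd4	q_pnd4	rho_pnd5	p_pnd5	q_pnd5
P04218	Cd200	31.068	-0.81	0.000017	0.00029	-0.60	0.0050	0.024
P06238	A2m	163.682	-0.58	0.0080	0.0182	-0.46	0.039	0.069
P0CG51	Ubb	34.347	-0.87	0.0000006	0.000039	-0.74	0.0002	0.0045
Q9JLD2	Serpini1	46.248	-0.50	0.0240	0.039	-0.55	0.012	0.035
B2RYG6	Otub1	31.250	0.58	0.0072	0.017	0.51	0.022	0.050
Q5U300	Ube1	117.713	0.71	0.0004	0.0027	0.52	0.018	0.043
Q5ZQU0	Sned1	151.301	0.75	0.00016	0.0014	0.50	0.025	0.053
Q9ET61	Cd93	68.737	0.48	0.0317	0.047	0.51	0.023	0.049
P07483	Fabp3	14.766	0.53	0.015	0.028	0.57	0.0093	0.032
P09006	Serpina3	46.622	-0.53	0.016	0.029	-0.70	0.00066	0.0080
P15429	Eno3	46.984	0.48	0.034	0.050	0.54	0.013	0.037
Q9QX79	Fetub	41.536	-0.54	0.013	0.025	-0.57	0.0091	0.032
Q99PS8	Hrg	59.012	0.46	0.040	0.055	0.57	0.0092	0.032
P08649	C4	192.042	-0.54	0.0132	0.025	-0.86	0.0000015	0.00014
P10959	Ces1	60.136	0.57	0.0093	0.019	0.71	0.00050	0.0074
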