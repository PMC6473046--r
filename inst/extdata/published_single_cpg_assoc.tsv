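cpg_id	gene	chrom	pos	tss_offset	meth_mean	meth_sd	beta_homa_ir	se_homa_ir	p_homa_ir	beta_glucose	se_glucose	p_glucose	beta_hba1c	se_hba1c	p_hba1c
CLOCK_56413146	CLOCK	chr4	56413146	158	0.78	1.11	0.160	0.101	0.115	2.135	1.144	0.068	0.031	0.048	0.516
CLOCK_56413153	CLOCK	chr4	56413153	151	1.06	1.19	0.165	0.092	0.073	1.894	1.042	0.076	0.044	0.044	0.329
CLOCK_56413164	CLOCK	chr4	56413164	140	1.90	1.35	0.067	0.092	0.465	2.207	1.003	0.033	0.058	0.042	0.169
CLOCK_56413207	CLOCK	chr4	56413207	97	1.15	1.03	0.204	0.102	0.044	1.433	1.167	0.226	0.038	0.049	0.444
CLOCK_56413229	CLOCK	chr4	56413229	75	2.20	1.04	0.292	0.100	0.003	2.863	1.130	0.015	0.087	0.047	0.073
CLOCK_56413260	CLOCK	chr4	56413260	44	0.65	1.18	0.137	0.079	0.085	0.760	0.910	0.408	-0.004	0.037	0.921
CLOCK_56413277	CLOCK	chr4	56413277	27	0.66	1.00	0.299	0.116	0.010	3.213	1.328	0.020	0.038	0.057	0.506
CLOCK_56413308	CLOCK	chr4	56413308	-4	1.36	1.24	0.129	0.086	0.132	2.326	0.970	0.021	0.051	0.041	0.216
CLOCK_56413348	CLOCK	chr4	56413348	-44	0.74	1.06	0.153	0.108	0.158	2.300	1.193	0.060	0.079	0.049	0.118
BMAL1_13298892	BMAL1	chr11	13298892	-453	0.85	1.11	0.530	0.179	0.003	5.586	2.097	0.011	0.228	0.088	0.013
BMAL1_13298896	BMAL1	chr11	13298896	-449	0.38	0.65	0.272	0.171	0.110	3.308	1.988	0.103	0.149	0.080	0.068
BMAL1_13298902	BMAL1	chr11	13298902	-443	1.24	0.99	0.169	0.218	0.439	3.999	2.441	0.108	0.230	0.097	0.022
BMAL1_13298923	BMAL1	chr11	13298923	-422	0.34	0.72	-0.389	0.222	0.080	-1.291	2.565	0.617	-0.105	0.112	0.353
BMAL1_13298932	BMAL1	chr11	13298932	-413	1.59	0.93	0.074	0.106	0.484	2.169	1.160	0.068	0.065	0.048	0.182
BMAL1_13298934	BMAL1	chr11	13298934	-411	0.74	0.89	0.254	0.122	0.037	2.795	1.404	0.053	0.114	0.058	0.054
BMAL1_13298975	BMAL1	chr11	13298975	-370	1.19	0.98	0.133	0.102	0.193	2.286	1.135	0.050	0.026	0.048	0.594
BMAL1_13299014	BMAL1	chr11	13299014	-331	2.56	1.48	0.046	0.068	0.501	1.426	0.739	0.060	0.039	0.031	0.207
BMAL1_13299033	BMAL1	chr11	13299033	-312	2.03	1.21	0.137	0.078	0.080	1.917	0.900	0.039	0.059	0.037	0.120
PER1_8055788	PER1	chr17	8055788	-36	1.29	1.03	0.155	0.138	0.261	2.873	1.519	0.065	0.030	0.065	0.643
PER1_8055794	PER1	chr17	8055794	-42	1.82	0.95	0.186	0.134	0.163	2.935	1.493	0.055	0.055	0.062	0.380
PER1_8055831	PER1	chr17	8055831	-79	1.16	0.96	-0.219	0.122	0.073	-0.597	1.409	0.674	0.027	0.058	0.646
PER1_8055883	PER1	chr17	8055883	-131	0.93	1.08	-0.186	0.104	0.074	-0.356	1.209	0.770	0.021	0.049	0.674
PER2_239197609	PER2	chr2	239197609	-361	1.19	0.79	0.123	0.118	0.299	2.315	1.360	0.096	0.068	0.056	0.235
PER2_239197627	PER2	chr2	239197627	-379	0.37	0.40	0.494	0.253	0.051	4.415	2.868	0.131	0.164	0.118	0.173
PER2_239197634	PER2	chr2	239197634	-386	0.41	0.51	0.509	0.213	0.017	6.068	2.382	0.014	0.127	0.102	0.217
PER2_239197649	PER2	chr2	239197649	-401	0.73	0.43	0.368	0.283	0.193	7.025	3.202	0.033	0.316	0.132	0.021
PER3_7844662	PER3	chr1	7844662	-53	41.73	5.94	-0.041	0.033	0.222	-0.207	0.379	0.589	-0.030	0.015	0.051
PER3_7844735	PER3	chr1	7844735	20	45.60	14.09	-0.014	0.008	0.068	0.074	0.091	0.418	0.001	0.004	0.860
PER3_7844743	PER3	chr1	7844743	28	44.36	14.96	0.015	0.009	0.091	-0.096	0.103	0.357	0.000	0.004	0.954
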