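aa	A	C	D	E	F	G	H	I	K	L	M	N	P	Q	R	S	T	V	W	Y
A	-2.288	-2.51	-0.703	-0.684	-2.561	-1.605	-0.783	-3.108	-0.587	-2.88	-2.293	-0.672	-1.257	-0.705	-0.409	-1.506	-1.517	-2.98	-1.462	-1.361
C	-2.51	-2.713	-0.894	-0.881	-2.775	-1.833	-1.008	-3.317	-0.78	-3.073	-2.502	-0.897	-1.485	-0.919	-0.606	-1.697	-1.72	-3.202	-1.691	-1.58
D	-0.703	-0.894	0.919	0.915	-0.993	-0.048	0.793	-1.5	1.037	-1.272	-0.717	0.885	0.311	0.894	1.213	0.11	0.068	-1.421	0.1	0.229
E	-0.684	-0.881	0.915	0.897	-1.008	-0.047	0.81	-1.483	1.038	-1.287	-0.735	0.881	0.324	0.913	1.22	0.098	0.049	-1.43	0.109	0.248
F	-2.561	-2.775	-0.993	-1.008	-2.897	-1.92	-1.063	-3.372	-0.867	-3.195	-2.629	-0.996	-1.547	-0.97	-0.682	-1.811	-1.85	-3.311	-1.762	-1.63
G	-1.605	-1.833	-0.048	-0.047	-1.92	-0.943	-0.102	-2.427	0.075	-2.239	-1.656	-0.017	-0.58	-0.022	0.259	-0.86	-0.881	-2.332	-0.79	-0.677
H	-0.783	-1.008	0.793	0.81	-1.063	-0.102	0.723	-1.605	0.911	-1.386	-0.797	0.83	0.248	0.799	1.09	-0.011	-0.022	-1.48	0.043	0.144
I	-3.108	-3.317	-1.5	-1.483	-3.372	-2.427	-1.605	-3.919	-1.386	-3.677	-3.1	-1.492	-2.081	-1.52	-1.211	-2.302	-2.32	-3.797	-2.286	-2.179
K	-0.587	-0.78	1.037	1.038	-0.867	0.075	0.911	-1.386	1.153	-1.15	-0.592	1.009	0.43	1.009	1.328	0.23	0.193	-1.296	0.221	0.345
L	-2.88	-3.073	-1.272	-1.287	-3.195	-2.239	-1.386	-3.677	-1.15	-3.472	-2.921	-1.31	-1.871	-1.282	-0.97	-2.087	-2.136	-3.619	-2.085	-1.947
M	-2.293	-2.502	-0.717	-0.735	-2.629	-1.656	-0.797	-3.1	-0.592	-2.921	-2.36	-0.731	-1.282	-0.7	-0.407	-1.536	-1.579	-3.045	-1.497	-1.362
N	-0.672	-0.897	0.885	0.881	-0.996	-0.017	0.83	-1.492	1.009	-1.31	-0.731	0.908	0.35	0.913	1.194	0.071	0.045	-1.407	0.138	0.257
P	-1.257	-1.485	0.311	0.324	-1.547	-0.58	0.248	-2.081	0.43	-1.871	-1.282	0.35	-0.227	0.324	0.611	-0.495	-0.507	-1.962	-0.433	-0.33
Q	-0.705	-0.919	0.894	0.913	-0.97	-0.022	0.799	-1.52	1.009	-1.282	-0.7	0.913	0.324	0.881	1.185	0.093	0.078	-1.393	0.12	0.223
R	-0.409	-0.606	1.213	1.22	-0.682	0.259	1.09	-1.211	1.328	-0.97	-0.407	1.194	0.611	1.185	1.503	0.408	0.377	-1.11	0.403	0.522
S	-1.506	-1.697	0.11	0.098	-1.811	-0.86	-0.011	-2.302	0.23	-2.087	-1.536	0.071	-0.495	0.093	0.408	-0.703	-0.75	-2.237	-0.708	-0.573
T	-1.517	-1.72	0.068	0.049	-1.85	-0.881	-0.022	-2.32	0.193	-2.136	-1.579	0.045	-0.507	0.078	0.377	-0.75	-0.797	-2.268	-0.723	-0.585
V	-2.98	-3.202	-1.421	-1.43	-3.311	-2.332	-1.48	-3.797	-1.296	-3.619	-3.045	-1.407	-1.962	-1.393	-1.11	-2.237	-2.268	-3.723	-2.175	-2.051
W	-1.462	-1.691	0.1	0.109	-1.762	-0.79	0.043	-2.286	0.221	-2.085	-1.497	0.138	-0.433	0.12	0.403	-0.708	-0.723	-2.175	-0.641	-0.535
Y	-1.361	-1.58	0.229	0.248	-1.63	-0.677	0.144	-2.179	0.345	-1.947	-1.362	0.257	-0.33	0.223	0.522	-0.573	-0.585	-2.051	-0.535	-0.433
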