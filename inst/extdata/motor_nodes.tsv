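label	x	y	z	hemisphere	pair_id
SMA_L	-6	-4	60	L	P01
SMA_R	6	-4	60	R	P01
CMA_L	-6	2	44	L	P02
CMA_R	6	2	44	R	P02
PMd_L	-26	-8	56	L	P03
PMd_R	26	-8	56	R	P03
PMv_L	-52	4	32	L	P04
PMv_R	52	4	32	R	P04
SFG_L	-20	36	44	L	P05
SFG_R	20	36	44	R	P05
SPL_L	-22	-54	60	L	P06
SPL_R	22	-54	60	R	P06
IPC_L	-48	-38	48	L	P07
IPC_R	48	-38	48	R	P07
S2_L	-54	-22	18	L	P08
S2_R	54	-22	18	R	P08
INS_L	-36	16	4	L	P09
INS_R	36	16	4	R	P09
PUT_L	-26	-2	2	L	P10
PUT_R	26	-2	2	R	P10
CAU_L	-14	8	10	L	P11
CAU_R	14	8	10	R	P11
CBH_L	-24	-58	-26	L	P12
CBH_R	24	-58	-26	R	P12
M1_L	-8	-28	66	L	
S1_L	-10	-40	64	L	
THA_L	-12	-18	8	L	
VER_M	2	-62	-32	M	
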