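# momaknock model, TSV dialect
#! biomass BIOMASS
#! glucose EX_glc
#! target EX_tgt
#! candidates R1,R2,R3,R4,R5,R6,R7,R8,R9,R10,R11,R12,R13,R14,R15,R16,R17,R18,Rtgt,Rbio
reaction	stoichiometry	lb	ub
R1	A:-1,H:1	0	100
R2	H:-1,T1:1	0	100
R3	T1:-1,T2:1	-100	100
R4	T2:-1,B1:2	-100	100
R5	H:-1,B1:1	0	5.5
R6	B1:-1,B2:2	0	100
R7	B2:-1,B3:1	0	100
R8	B3:-1,B4:1	0	100
R9	B4:-1,B5:2	0	100
R10	B5:-1,B6:1	0	100
R11	T1:1,B1:-1	0	100
R12	T1:1,B5:-1	0	100
R13	B4:-1,B5:2	0	100
R14	H:1,B1:-1	0	100
R15	B3:2,B5:-1	0	100
R16	T1:1,B2:-1	0	100
R17	T1:-1,B2:2	0	100
R18	B1:-1,B5:2	-100	100
Rtgt	T2:-1,TGT:1	0	100
Rbio	B6:-1,BIO:1	0	100
EX_glc	A:1	0	20
EX_tgt	TGT:-1	0	1000
BIOMASS	A:-0.1,BIO:-1	0	1000
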