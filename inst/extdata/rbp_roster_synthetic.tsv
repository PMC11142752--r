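rbp	family
PTBP1	PTB
PTBP2	PTB
SRSF1	SR
SRSF2	SR
SRSF3	SR
SRSF4	SR
SRSF5	SR
SRSF6	SR
SRSF7	SR
SRSF9	SR
SRSF10	SR
SRSF11	SR
HNRNPA1	hnRNP
HNRNPA2B1	hnRNP
HNRNPC	hnRNP
HNRNPD	hnRNP
HNRNPF	hnRNP
HNRNPH1	hnRNP
HNRNPK	hnRNP
HNRNPL	hnRNP
HNRNPM	hnRNP
HNRNPU	hnRNP
RBFOX1	RBFOX
RBFOX2	RBFOX
RBFOX3	RBFOX
NOVA1	NOVA
NOVA2	NOVA
ELAVL1	ELAV
ELAVL2	ELAV
ELAVL3	ELAV
ELAVL4	ELAV
CELF1	CELF
CELF2	CELF
CELF4	CELF
MBNL1	MBNL
MBNL2	MBNL
MBNL3	MBNL
QKI	STAR
KHDRBS1	STAR
KHDRBS2	STAR
KHDRBS3	STAR
TIA1	TIA
TIAL1	TIA
U2AF1	U2AF
U2AF2	U2AF
SF1	SF
SF3B1	SF3
SF3A1	SF3
SRRM1	SRRM
SRRM2	SRRM
SRRM4	SRRM
SNRPB	Sm
SNRPD1	Sm
SNRPD2	Sm
SNRPD3	Sm
SNRNP70	snRNP
ESRP1	ESRP
ESRP2	ESRP
TRA2A	TRA2
TRA2B	TRA2
FUS	FET
TAF15	FET
EWSR1	FET
TARDBP	TDP
MATR3	MATR
SAMD4A	SAMD
PCBP1	PCBP
PCBP2	PCBP
RBM5	RBM
RBM10	RBM
RBM20	RBM
RBM24	RBM
RBM38	RBM
RBM39	RBM
RBM47	RBM
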