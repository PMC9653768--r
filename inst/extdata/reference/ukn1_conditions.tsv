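compound_id	bucket	concentration_label	truth	cytotoxic	up	down
AMP	1x	1x	non_teratogen	FALSE	0	0
ASC	1x	1x	non_teratogen	FALSE	0	0
BSP	1x	1x	non_teratogen	FALSE	0	0
CPA	1x	1x	non_teratogen	FALSE	0	0
DEX	1x	1x	non_teratogen	FALSE	0	0
DPH	1x	1x	non_teratogen	FALSE	0	0
DOA	1x	1x	non_teratogen	FALSE	0	0
FAM	1x	1x	non_teratogen	FALSE	0	0
FOA	1x	1x	non_teratogen	FALSE	0	0
LEV	1x	1x	non_teratogen	FALSE	18	20
LIO	1x	1x	non_teratogen	FALSE	0	0
MAG	1x	1x	non_teratogen	FALSE	0	0
MET	1x	1x	non_teratogen	FALSE	0	0
RAN	1x	1x	non_teratogen	FALSE	0	0
RET	1x	1x	non_teratogen	FALSE	0	0
SUC	1x	1x	non_teratogen	FALSE	0	0
9RA	1x	1x	teratogen	FALSE	1956	1785
ACI	1x	1x	teratogen	FALSE	1803	1604
ACD	1x	1x	teratogen	TRUE	NA	NA
ATO	1x	1x	teratogen	TRUE	NA	NA
CMZ	1x	1x	teratogen	FALSE	0	0
DXR	1x	1x	teratogen	TRUE	NA	NA
ENT	1x	1x	teratogen	FALSE	48	30
FPV	1x	1x	teratogen	FALSE	0	0
ISO	1x	1x	teratogen	FALSE	1029	703
LFL	1x	1x	teratogen	FALSE	614	415
LTH	1x	1x	teratogen	FALSE	0	0
MTX	1x	1x	teratogen	FALSE	435	209
MEM	1x	1x	teratogen	FALSE	0	0
PAN	1x	1x	teratogen	TRUE	NA	NA
PAX	1x	1x	teratogen	FALSE	0	0
PHE	1x	1x	teratogen	FALSE	0	0
TER	1x	1x	teratogen	FALSE	1829	1394
THD	1x	1x	teratogen	FALSE	41	21
TSA	1x	1x	teratogen	FALSE	4	0
VPA	1x	1x	teratogen	FALSE	630	364
VIN	1x	1x	teratogen	TRUE	NA	NA
VIS	1x	1x	teratogen	FALSE	0	0
VST	1x	1x	teratogen	TRUE	NA	NA
AMP	20x	20x	non_teratogen	FALSE	0	0
ASC	20x	20x	non_teratogen	FALSE	0	0
BSP	20x	20x	non_teratogen	FALSE	0	0
CPA	20x	20x	non_teratogen	FALSE	0	0
DEX	20x	20x	non_teratogen	FALSE	0	0
DPH	20x	20x	non_teratogen	FALSE	0	0
DOA	20x	20x	non_teratogen	FALSE	0	0
FAM	20x	20x	non_teratogen	FALSE	0	0
FOA	20x	20x	non_teratogen	FALSE	0	0
LEV	20x	20x	non_teratogen	FALSE	0	0
LIO	20x	20x	non_teratogen	FALSE	27	57
MAG	20x	20x	non_teratogen	FALSE	13	3
MET	20x	20x	non_teratogen	FALSE	0	2
RAN	20x	20x	non_teratogen	FALSE	0	0
SUC	20x	20x	non_teratogen	FALSE	0	0
9RA	20x	20x	teratogen	FALSE	2426	1887
ACI	20x	20x	teratogen	FALSE	2309	1795
ACD	20x	20x	teratogen	TRUE	NA	NA
ATO	20x	20x	teratogen	TRUE	NA	NA
CMZ	20x	10x	teratogen	FALSE	910	591
DXR	20x	20x	teratogen	TRUE	NA	NA
ENT	20x	20x	teratogen	TRUE	NA	NA
FPV	20x	20x	teratogen	FALSE	1551	1290
ISO	20x	20x	teratogen	TRUE	NA	NA
LTH	20x	20x	teratogen	TRUE	NA	NA
MTX	20x	20x	teratogen	FALSE	687	622
MEM	20x	20x	teratogen	FALSE	0	0
PAN	20x	20x	teratogen	TRUE	NA	NA
PAX	20x	20x	teratogen	TRUE	NA	NA
RET	20x	20x	teratogen	FALSE	1032	936
THD	20x	20x	teratogen	FALSE	0	0
TSA	20x	20x	teratogen	TRUE	NA	NA
VPA	20x	1.67x	teratogen	FALSE	878	685
VIN	20x	20x	teratogen	TRUE	NA	NA
VST	20x	20x	teratogen	TRUE	NA	NA
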