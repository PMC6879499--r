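protein	pdb	resolution	degree
14-3-3	4IHL	2.2	27
ADYCA	4CLT	1.95	1
AKT	4GV1	1.49	53
AMPK	2UV4	1.33	20
CAMKK2	2ZV2	2.4	3
eIF4E	4TPW	1.5	18
EP300	3BIY	1.7	16
ERK1/2	4ZZN	1.33	39
GRB2	3C7I	1.7	16
GSK3	1Q5K	1.94	29
HPH	4BQY	1.5	34
KEAP1	4IQK	1.97	3
MDM2	4OGN	1.37	11
MEK	3EQI	1.9	14
mTOR	3FAP	1.85	55
NAMPT	4O13	1.75	2
p53	2VUK	1.5	42
PARG	4B1H	2	1
PARP1	4ZZZ	1.9	8
PDE4B	4KP6	1.5	2
PDK1	5ACK	1.24	29
PGDH	2GDZ	1.6	50
PGES	4YL1	1.4	15
PI3K	4L23	2.5	41
PIN1	3I6C	1.3	7
PKC_alpha	4RA4	2.63	31
PLA2	3U8D	1.80	54
PP1A	3E7B	1.7	8
PP2A	2IE4	2.6	18
PPAR_gamma	3U9Q	1.52	21
PTEN	1D5R	2.1	32
Rac	1MH1	1.38	18
Raf	4XV9	2	13
Rap1a	4KVG	1.65	15
Ras	3K8Y	1.3	28
Rheb	3T5G	1.7	24
RhoA	1KMQ	1.55	19
S6K1	2Z7R	2	30
SGK1	3HDM	2.6	25
SIRT6	3ZG6	2.2	4
SOS	4NYJ	2.85	22
TK_receptor	4IBM	1.8	17
TNFR	1FT4	2.9	5
tyrRS	4Q93	2.1	1
ULK1	4WNO	1.56	10
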