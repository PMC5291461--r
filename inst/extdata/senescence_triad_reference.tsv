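gene_id	fc	mirnas
EIF4EBP2	3.0	hsa-miR-7-5p,hsa-miR-193a-5p,hsa-miR-335-5p
HECW2	4.2	hsa-miR-7-5p,hsa-miR-25-3p,hsa-miR-505-3p
CADM1	8.2	hsa-miR-7-5p,hsa-miR-505-3p
CNNM2	2.9	hsa-miR-335-5p,hsa-miR-505-3p
CPEB2	2.6	hsa-miR-7-5p,hsa-miR-505-3p
CRY2	2.2	hsa-miR-7-5p,hsa-miR-17-5p
DAAM1	2.5	hsa-miR-130b-3p,hsa-miR-335-5p
DGKH	2.5	hsa-miR-130b-3p,hsa-miR-505-3p
DOK6	2.2	hsa-miR-17-5p,hsa-miR-335-5p
EGR2	2.8	hsa-miR-17-5p,hsa-miR-25-3p
FAM134C	2.2	hsa-miR-17-5p,hsa-miR-335-5p
GRIN2A	2.0	hsa-miR-7-5p,hsa-miR-130b-3p
HPCAL4	7.6	hsa-miR-7-5p,hsa-miR-335-5p
IL6ST	2.2	hsa-miR-130b-3p,hsa-miR-505-3p
KLHL28	2.4	hsa-miR-7-5p,hsa-miR-335-5p
MEF2D	2.7	hsa-miR-335-5p,hsa-miR-505-3p
MYO1D	5.9	hsa-miR-193a-5p,hsa-miR-335-5p
NR4A3	2.1	hsa-miR-7-5p,hsa-miR-335-5p
OXR1	2.9	hsa-miR-7-5p,hsa-miR-17-5p
PGM2L1	4.8	hsa-miR-17-5p,hsa-miR-130b-3p
PIP4K2C	2.1	hsa-miR-25-3p,hsa-miR-505-3p
PPARGC1B	2.6	hsa-miR-7-5p,hsa-miR-505-3p
RAB11FIP5	2.8	hsa-miR-7-5p,hsa-miR-17-5p
RNF141	2.4	hsa-miR-7-5p,hsa-miR-335-5p
SEMA6D	5.9	hsa-miR-7-5p,hsa-miR-193a-5p
ZDHHC8	5.2	hsa-miR-17-5p,hsa-miR-335-5p
ZMAT3	3.4	hsa-miR-7-5p,hsa-miR-130b-3p
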