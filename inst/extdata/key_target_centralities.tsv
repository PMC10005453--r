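gene_symbol	degree	betweenness	closeness	relevance_score
STAT3	31	0.059	0.804	3.767
VEGFA	29	0.058	0.774	7.895
IL6	28	0.067	0.759	8.536
SRC	27	0.078	0.745	2.834
AKT1	27	0.041	0.745	11.390
EGFR	26	0.040	0.732	1.950
TNF	26	0.051	0.732	7.125
MMP9	23	0.026	0.695	3.936
PTPN11	21	0.019	0.672	2.467
CTNNB1	19	0.018	0.651	4.002
PIK3CA	19	0.014	0.641	9.507
ALB	18	0.028	0.641	7.226
HIF1A	17	0.009	0.631	2.834
FGF2	17	0.009	0.631	3.380
TLR4	17	0.012	0.631	7.630
NFKB1	16	0.017	0.621	2.011
CXCR4	15	0.016	0.612	2.595
ICAM1	15	0.011	0.612	5.260
IL2	14	0.006	0.603	2.973
MMP2	14	0.007	0.603	3.102
JAK2	14	0.008	0.603	36.781
PDGFRB	13	0.004	0.594	2.117
PTGS2	13	0.003	0.594	6.734
KDR	12	0.003	0.577	2.177
MTOR	12	0.006	0.569	2.209
NOS3	12	0.006	0.586	7.956
PPARG	11	0.003	0.577	2.515
ESR1	11	0.002	0.554	3.424
MMP3	11	0.003	0.569	3.432
VCAM1	11	0.007	0.577	4.597
PLG	11	0.005	0.562	12.016
SERPINE1	11	0.008	0.562	21.828
SYK	10	0.005	0.562	2.066
BCL2L1	10	0.003	0.569	2.575
ITGB2	10	0.006	0.569	2.812
PDGFRA	10	0.001	0.569	5.720
MMP1	9	0.000	0.539	2.561
CASP8	8	0.002	0.554	2.362
PIK3CG	8	0.002	0.519	3.213
APP	7	0.003	0.539	2.270
F3	7	0.002	0.506	23.179
F2	6	0.005	0.526	58.855
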