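gene	rank	median_sam_score	log2fc_breast	sam_score_breast	log2fc_melanoma	sam_score_melanoma	log2fc_lymphoma	sam_score_lymphoma
NKX6-2	1	8.6	5.2	8.6	5.6	10.9	6.5	5.0
GFAP	2	8.4	3.7	10.4	2.9	8.4	4.3	3.9
STMN4	3	6.9	3.3	6.9	3.7	9.0	4.9	4.8
SOX2-OT	4	5.9	2.4	5.8	3.1	6.3	5.0	5.9
LOC284570	5	5.7	2.1	6.0	2.4	5.7	3.4	4.2
GRM3	6	5.5	2.6	9.2	1.8	5.5	3.4	4.5
CNTN2	7	5.4	3.3	5.4	5.1	8.7	5.6	3.8
CACNG7	8	5.3	1.4	6.3	1.2	5.3	2.0	4.1
MT3	9	5.3	2.3	6.4	1.6	5.3	2.4	4.9
GPR37L1	10	5.3	2.5	5.3	3.8	6.5	4.7	4.4
NCAM1	11	5.3	2.7	7.6	2.7	4.0	4.9	5.3
FAM123A	12	5.2	2.5	5.2	3.3	7.0	4.8	5.2
AQP4	13	5.2	2.7	5.2	3.1	8.7	3.0	4.2
MOBP	14	5.1	2.0	5.1	2.7	7.1	3.5	3.7
CLDN11	15	4.9	1.7	3.3	3.2	4.9	4.5	5.5
GAP43	16	4.5	3.3	10.2	3.1	4.5	4.7	4.5
NCAN	17	4.4	1.4	2.9	1.3	4.8	2.6	4.4
DNER	18	4.4	2.2	4.0	2.6	4.4	4.0	5.3
TMEM229A	18	4.3	2.0	5.2	2.5	4.3	3.2	3.9
KLK6	20	4.2	3.7	4.2	3.8	6.3	3.9	3.8
OMG	21	4.2	1.7	4.2	2.1	3.8	3.3	4.6
KIF5C	22	4.1	1.4	2.9	2.6	4.1	3.5	5.9
MAG	23	3.8	1.6	3.7	1.6	3.8	2.7	4.0
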