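GCA_SYN0001__4_glim_g1	GCA_SYN0002__3_glim_g1	82.4773413897281	331	58	0	1	331	1	331	6.30957e-19	546	331	331
GCA_SYN0001__4_glim_g1	GCA_SYN0003__3_glim_g1	79.1540785498489	331	69	0	1	331	1	331	3.41455e-18	524	331	331
GCA_SYN0002__3_glim_g1	GCA_SYN0001__4_glim_g1	82.4773413897281	331	58	0	1	331	1	331	6.30957e-19	546	331	331
GCA_SYN0002__3_glim_g1	GCA_SYN0003__3_glim_g1	80.6646525679758	331	64	0	1	331	1	331	1.58489e-18	534	331	331
GCA_SYN0003__3_glim_g1	GCA_SYN0001__4_glim_g1	79.1540785498489	331	69	0	1	331	1	331	3.41455e-18	524	331	331
GCA_SYN0003__3_glim_g1	GCA_SYN0002__3_glim_g1	80.6646525679758	331	64	0	1	331	1	331	1.58489e-18	534	331	331
GCA_SYN0001__4_glim_g2	GCA_SYN0002__3_glim_g2	79.8449612403101	387	78	0	1	387	1	387	2.51189e-21	618	387	387
GCA_SYN0001__4_glim_g2	GCA_SYN0003__3_glim_g2	75.7105943152455	387	94	0	1	387	1	387	2.92864e-20	586	387	387
GCA_SYN0002__3_glim_g2	GCA_SYN0001__4_glim_g2	79.8449612403101	387	78	0	1	387	1	387	2.51189e-21	618	387	387
GCA_SYN0002__3_glim_g2	GCA_SYN0003__3_glim_g2	78.5529715762274	387	83	0	1	387	1	387	5.41170e-21	608	387	387
GCA_SYN0003__3_glim_g2	GCA_SYN0001__4_glim_g2	75.7105943152455	387	94	0	1	387	1	387	2.92864e-20	586	387	387
GCA_SYN0003__3_glim_g2	GCA_SYN0002__3_glim_g2	78.5529715762274	387	83	0	1	387	1	387	5.41170e-21	608	387	387
GCA_SYN0001__3_glim_g1	GCA_SYN0002__2_glim_g1	81.8385650224215	446	81	0	1	446	1	446	4.64159e-25	730	446	446
GCA_SYN0001__3_glim_g1	GCA_SYN0003__2_glim_g1	85.2017937219731	446	66	0	1	446	1	446	4.64159e-26	760	446	446
GCA_SYN0002__2_glim_g1	GCA_SYN0001__3_glim_g1	81.8385650224215	446	81	0	1	446	1	446	4.64159e-25	730	446	446
GCA_SYN0002__2_glim_g1	GCA_SYN0003__2_glim_g1	81.8385650224215	446	81	0	1	446	1	446	4.64159e-25	730	446	446
GCA_SYN0003__2_glim_g1	GCA_SYN0001__3_glim_g1	85.2017937219731	446	66	0	1	446	1	446	4.64159e-26	760	446	446
GCA_SYN0003__2_glim_g1	GCA_SYN0002__2_glim_g1	81.8385650224215	446	81	0	1	446	1	446	4.64159e-25	730	446	446
GCA_SYN0001__3_glim_g2	GCA_SYN0002__2_glim_g2	84.3984962406015	532	83	0	1	532	1	532	1.16591e-30	898	532	532
GCA_SYN0001__3_glim_g2	GCA_SYN0003__2_glim_g2	82.7067669172932	532	92	0	1	532	1	532	4.64159e-30	880	532	532
GCA_SYN0002__2_glim_g2	GCA_SYN0001__3_glim_g2	84.3984962406015	532	83	0	1	532	1	532	1.16591e-30	898	532	532
GCA_SYN0002__2_glim_g2	GCA_SYN0003__2_glim_g2	83.0827067669173	532	90	0	1	532	1	532	3.41455e-30	884	532	532
GCA_SYN0003__2_glim_g2	GCA_SYN0001__3_glim_g2	82.7067669172932	532	92	0	1	532	1	532	4.64159e-30	880	532	532
GCA_SYN0003__2_glim_g2	GCA_SYN0002__2_glim_g2	83.0827067669173	532	90	0	1	532	1	532	3.41455e-30	884	532	532
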