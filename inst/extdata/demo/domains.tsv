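protein_id	accession	name	evalue	bitscore	ali_start	ali_end
GCA_SYN0001__1_glim_g1	PF00501	PF00501	5.12885630828753e-29	134.3	0	50
GCA_SYN0001__1_glim_g1	PF00668	PF00668	2.7841638877288e-31	204.2	0	50
GCA_SYN0001__1_glim_g1	PF00550	PF00550	4.12898124778185e-45	252.9	0	50
GCA_SYN0002__1_glim_g1	PF00494	PF00494	4.43029957999442e-40	249.8	0	50
GCA_SYN0002__1_glim_g2	PF01593	PF01593	1.76148205934829e-42	256.8	0	50
GCA_SYN0002__1_glim_g2	PF99010	PF99010	9.79519709388761e-24	190	0	50
GCA_SYN0003__1_glim_g1	PF05114	PF05114	6.47588773766846e-25	271.1	0	50
GCA_SYN0001__2_glim_g1	PF00109	PF00109	1.23657354776985e-38	218.4	0	50
GCA_SYN0001__2_glim_g1	PF02801	PF02801	3.87517447100633e-34	149.7	0	50
GCA_SYN0001__3_glim_g1	PF04183	PF04183	5.48953391844245e-45	265.6	0	50
GCA_SYN0001__3_glim_g1	PF06276	PF06276	1.88679566871547e-22	111.9	0	50
GCA_SYN0002__2_glim_g1	PF04183	PF04183	1.37583597820265e-22	116.7	0	50
GCA_SYN0002__2_glim_g1	PF06276	PF06276	1.09430879609646e-33	109.1	0	50
GCA_SYN0003__2_glim_g1	PF04183	PF04183	2.72329262228014e-25	248.8	0	50
GCA_SYN0003__2_glim_g1	PF06276	PF06276	2.22784782665537e-34	156.4	0	50
GCA_SYN0001__4_glim_g1	PF00501	PF00501	1.52150601904185e-42	135	0	50
GCA_SYN0001__4_glim_g1	PF00550	PF00550	6.77733967016255e-50	293.3	0	50
GCA_SYN0002__3_glim_g1	PF00501	PF00501	6.42187785438266e-42	107.9	0	50
GCA_SYN0002__3_glim_g1	PF00550	PF00550	3.81779894984492e-45	287.2	0	50
GCA_SYN0003__3_glim_g1	PF00501	PF00501	1.20491826768722e-46	240.2	0	50
GCA_SYN0003__3_glim_g1	PF00550	PF00550	8.97066592298066e-39	113.1	0	50
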