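protein_id	subject_id	group	evalue
GCA_SYN0001__1_glim_g1	DIK_GCA_SYN0001__1_glim_g1	Dikarya	3.59599181967312e-58
GCA_SYN0001__1_glim_g1	BACT_GCA_SYN0001__1_glim_g1	Bacteria	3.12222522276556e-51
GCA_SYN0001__1_glim_g2	DIK_GCA_SYN0001__1_glim_g2	Dikarya	1.2205939639958e-55
GCA_SYN0001__1_glim_g2	BACT_GCA_SYN0001__1_glim_g2	Bacteria	2.29252666255649e-46
GCA_SYN0001__1_glim_g3	DIK_GCA_SYN0001__1_glim_g3	Dikarya	7.98639085418196e-53
GCA_SYN0001__1_glim_g3	BACT_GCA_SYN0001__1_glim_g3	Bacteria	1.29285387699998e-40
GCA_SYN0002__1_glim_g1	DIK_GCA_SYN0002__1_glim_g1	Dikarya	7.0478471846566e-52
GCA_SYN0002__1_glim_g1	BACT_GCA_SYN0002__1_glim_g1	Bacteria	1.14896159182272e-41
GCA_SYN0002__1_glim_g2	DIK_GCA_SYN0002__1_glim_g2	Dikarya	9.11659339403766e-59
GCA_SYN0002__1_glim_g2	BACT_GCA_SYN0002__1_glim_g2	Bacteria	1.88294769276473e-47
GCA_SYN0003__1_glim_g1	DIK_GCA_SYN0003__1_glim_g1	Dikarya	6.30324687729275e-59
GCA_SYN0003__1_glim_g1	BACT_GCA_SYN0003__1_glim_g1	Bacteria	5.79051098157918e-53
GCA_SYN0003__1_glim_g2	DIK_GCA_SYN0003__1_glim_g2	Dikarya	5.62454703855336e-45
GCA_SYN0003__1_glim_g2	BACT_GCA_SYN0003__1_glim_g2	Bacteria	2.79551433860315e-35
GCA_SYN0003__1_glim_g3	DIK_GCA_SYN0003__1_glim_g3	Dikarya	6.89755176163585e-35
GCA_SYN0003__1_glim_g3	BACT_GCA_SYN0003__1_glim_g3	Bacteria	1.84248594175495e-29
GCA_SYN0001__2_glim_g1	DIK_GCA_SYN0001__2_glim_g1	Dikarya	3.36413377339959e-33
GCA_SYN0001__2_glim_g1	BACT_GCA_SYN0001__2_glim_g1	Bacteria	2.85503121308009e-23
GCA_SYN0001__2_glim_g2	DIK_GCA_SYN0001__2_glim_g2	Dikarya	6.72753665490005e-58
GCA_SYN0001__2_glim_g2	BACT_GCA_SYN0001__2_glim_g2	Bacteria	1.24307904502604e-47
GCA_SYN0001__2_glim_g3	DIK_GCA_SYN0001__2_glim_g3	Dikarya	7.44957448561625e-53
GCA_SYN0001__2_glim_g3	BACT_GCA_SYN0001__2_glim_g3	Bacteria	1.28395266524389e-44
GCA_SYN0001__3_glim_g1	DIK_GCA_SYN0001__3_glim_g1	Dikarya	2.78553178132498e-51
GCA_SYN0001__3_glim_g1	BACT_GCA_SYN0001__3_glim_g1	Bacteria	5.72557304575201e-36
GCA_SYN0001__3_glim_g2	DIK_GCA_SYN0001__3_glim_g2	Dikarya	6.02525724433578e-31
GCA_SYN0001__3_glim_g2	BACT_GCA_SYN0001__3_glim_g2	Bacteria	2.56517778452627e-19
GCA_SYN0002__2_glim_g1	DIK_GCA_SYN0002__2_glim_g1	Dikarya	4.4324178641541e-49
GCA_SYN0002__2_glim_g1	BACT_GCA_SYN0002__2_glim_g1	Bacteria	1.81935682679154e-38
GCA_SYN0002__2_glim_g2	DIK_GCA_SYN0002__2_glim_g2	Dikarya	7.53475289652811e-32
GCA_SYN0002__2_glim_g2	BACT_GCA_SYN0002__2_glim_g2	Bacteria	1.01373742996361e-25
GCA_SYN0003__2_glim_g1	DIK_GCA_SYN0003__2_glim_g1	Dikarya	1.87370881811593e-59
GCA_SYN0003__2_glim_g1	BACT_GCA_SYN0003__2_glim_g1	Bacteria	6.97192493211381e-52
GCA_SYN0003__2_glim_g2	DIK_GCA_SYN0003__2_glim_g2	Dikarya	7.43022027945016e-60
GCA_SYN0003__2_glim_g2	BACT_GCA_SYN0003__2_glim_g2	Bacteria	1.84560959565083e-50
GCA_SYN0001__4_glim_g1	DIK_GCA_SYN0001__4_glim_g1	Dikarya	3.95869965957198e-41
GCA_SYN0001__4_glim_g1	BACT_GCA_SYN0001__4_glim_g1	Bacteria	1.29446800118156e-30
GCA_SYN0001__4_glim_g2	DIK_GCA_SYN0001__4_glim_g2	Dikarya	6.79055492405859e-32
GCA_SYN0001__4_glim_g2	BACT_GCA_SYN0001__4_glim_g2	Bacteria	3.09383830918673e-23
GCA_SYN0002__3_glim_g1	DIK_GCA_SYN0002__3_glim_g1	Dikarya	7.27897266188479e-36
GCA_SYN0002__3_glim_g1	BACT_GCA_SYN0002__3_glim_g1	Bacteria	1.3869469191574e-24
GCA_SYN0002__3_glim_g2	DIK_GCA_SYN0002__3_glim_g2	Dikarya	5.39239583301002e-51
GCA_SYN0002__3_glim_g2	BACT_GCA_SYN0002__3_glim_g2	Bacteria	3.16424817249452e-45
GCA_SYN0003__3_glim_g1	DIK_GCA_SYN0003__3_glim_g1	Dikarya	1.01238867310816e-47
GCA_SYN0003__3_glim_g1	BACT_GCA_SYN0003__3_glim_g1	Bacteria	8.61271811710432e-40
GCA_SYN0003__3_glim_g2	DIK_GCA_SYN0003__3_glim_g2	Dikarya	7.26777642496413e-39
GCA_SYN0003__3_glim_g2	BACT_GCA_SYN0003__3_glim_g2	Bacteria	9.28058192732929e-31
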