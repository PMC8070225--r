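{
  "family_of": {
    "GCA_SYN0001__1_glim_g1": "NRPS",
    "GCA_SYN0002__1_glim_g1": "SQS",
    "GCA_SYN0001__2_glim_g1": "PKS",
    "GCA_SYN0001__3_glim_g1": "sid_pos1",
    "GCA_SYN0001__3_glim_g2": "sid_pos2",
    "GCA_SYN0002__2_glim_g1": "sid_pos1",
    "GCA_SYN0002__2_glim_g2": "sid_pos2",
    "GCA_SYN0003__2_glim_g1": "sid_pos1",
    "GCA_SYN0003__2_glim_g2": "sid_pos2",
    "GCA_SYN0001__4_glim_g1": "nps_pos1",
    "GCA_SYN0001__4_glim_g2": "nps_pos2",
    "GCA_SYN0002__3_glim_g1": "nps_pos1",
    "GCA_SYN0002__3_glim_g2": "nps_pos2",
    "GCA_SYN0003__3_glim_g1": "nps_pos1",
    "GCA_SYN0003__3_glim_g2": "nps_pos2"
  },
  "group_of": {
    "GCA_SYN0001__1_glim": "",
    "GCA_SYN0002__1_glim": "",
    "GCA_SYN0003__1_glim": "",
    "GCA_SYN0001__2_glim": "",
    "GCA_SYN0001__3_glim": "sid",
    "GCA_SYN0002__2_glim": "sid",
    "GCA_SYN0003__2_glim": "sid",
    "GCA_SYN0001__4_glim": "nps",
    "GCA_SYN0002__3_glim": "nps",
    "GCA_SYN0003__3_glim": "nps"
  },
  "type_of": {
    "GCA_SYN0001__1_glim": "NRPS",
    "GCA_SYN0002__1_glim": "terpene",
    "GCA_SYN0003__1_glim": "bacteriocin",
    "GCA_SYN0001__2_glim": "PKS",
    "GCA_SYN0001__3_glim": "siderophore",
    "GCA_SYN0002__2_glim": "siderophore",
    "GCA_SYN0003__2_glim": "siderophore",
    "GCA_SYN0001__4_glim": "NRPS-like",
    "GCA_SYN0002__3_glim": "NRPS-like",
    "GCA_SYN0003__3_glim": "NRPS-like"
  },
  "origin_of": {
    "GCA_SYN0001__1_glim_g1": "fungal",
    "GCA_SYN0001__1_glim_g2": "fungal",
    "GCA_SYN0001__1_glim_g3": "fungal",
    "GCA_SYN0002__1_glim_g1": "fungal",
    "GCA_SYN0002__1_glim_g2": "fungal",
    "GCA_SYN0003__1_glim_g1": "fungal",
    "GCA_SYN0003__1_glim_g2": "fungal",
    "GCA_SYN0003__1_glim_g3": "fungal",
    "GCA_SYN0001__2_glim_g1": "fungal",
    "GCA_SYN0001__2_glim_g2": "fungal",
    "GCA_SYN0001__2_glim_g3": "fungal",
    "GCA_SYN0001__3_glim_g1": "fungal",
    "GCA_SYN0001__3_glim_g2": "fungal",
    "GCA_SYN0002__2_glim_g1": "fungal",
    "GCA_SYN0002__2_glim_g2": "fungal",
    "GCA_SYN0003__2_glim_g1": "fungal",
    "GCA_SYN0003__2_glim_g2": "fungal",
    "GCA_SYN0001__4_glim_g1": "fungal",
    "GCA_SYN0001__4_glim_g2": "fungal",
    "GCA_SYN0002__3_glim_g1": "fungal",
    "GCA_SYN0002__3_glim_g2": "fungal",
    "GCA_SYN0003__3_glim_g1": "fungal",
    "GCA_SYN0003__3_glim_g2": "fungal"
  },
  "identity_of": {
    "GCA_SYN0001__3_glim": 85,
    "GCA_SYN0002__2_glim": 85,
    "GCA_SYN0003__2_glim": 85,
    "GCA_SYN0001__4_glim": 80,
    "GCA_SYN0002__3_glim": 80,
    "GCA_SYN0003__3_glim": 80
  },
  "copy_number": {
    "assembly_id": ["GCA_SYN0001", "GCA_SYN0002", "GCA_SYN0003", "GCA_SYN0001", "GCA_SYN0002", "GCA_SYN0003", "GCA_SYN0001", "GCA_SYN0001", "GCA_SYN0001", "GCA_SYN0002", "GCA_SYN0003", "GCA_SYN0001", "GCA_SYN0002", "GCA_SYN0003", "GCA_SYN0002"],
    "family": ["nps_pos1", "nps_pos1", "nps_pos1", "nps_pos2", "nps_pos2", "nps_pos2", "NRPS", "PKS", "sid_pos1", "sid_pos1", "sid_pos1", "sid_pos2", "sid_pos2", "sid_pos2", "SQS"],
    "n": [1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1]
  },
  "seed": 42
}
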