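domain	coarse	fine	n_sequences	n_otus	pct_seq_coverage	pct_otu_coverage
bacteria	Aerosol	Aerosol	3472	1068	79.5	33.2
bacteria	Aquatic	Brackish	1094	646	54.6	23.1
bacteria	Aquatic	Brackish sediment	390	243	54.4	26.7
bacteria	Aquatic	Freshwater	21647	6689	80.8	37.7
bacteria	Aquatic	Freshwater sediment	6733	3549	63.0	29.8
bacteria	Aquatic	Marine	134727	14287	94.3	46.7
bacteria	Aquatic	Marine sediment	27801	9567	79.6	40.8
bacteria	Aquatic	Hydrothermal vent	10860	4216	75.4	36.5
bacteria	Aquatic	Ice	2073	936	71.2	36.1
bacteria	Aquatic	Other	8760	3802	71.7	34.8
bacteria	Built	Digesters	33152	8949	82.9	36.8
bacteria	Built	Food-associated	11813	1632	92.0	41.9
bacteria	Built	Industrial/mining	16582	6099	76.6	36.3
bacteria	Built	Pollution-associated	38696	10602	84.1	41.9
bacteria	Built	Other	8556	2730	79.1	34.7
bacteria	Plant-associated	Root	19695	5052	84.3	38.7
bacteria	Plant-associated	Surface	4892	1385	82.7	38.8
bacteria	Plant-associated	Other	9753	3217	78.8	35.8
bacteria	Soil	Agriculture	10051	4017	73.6	34.0
bacteria	Soil	Desert	3042	1280	73.7	37.5
bacteria	Soil	Permafrost	1922	870	73.0	40.3
bacteria	Soil	Other	59855	17166	82.9	40.4
bacteria	Host-associated	Vertebrate	773045	42497	96.1	29.5
bacteria	Host-associated	Arthropod	13209	3688	81.8	34.7
bacteria	Host-associated	Other invertebrate	7476	2626	78.0	37.3
bacteria	Host-associated	Other	10855	1754	89.2	33.4
bacteria	Other	Other	19414	5930	81.6	39.9
bacteria	NoSource	NoSource	151669	14144	94.9	45.6
bacteria	Total		1411234	108950	94.5	29.2
archaea	Aerosol	Aerosol	2	1	100.0	100.0
archaea	Aquatic	Brackish	1368	314	87.4	44.9
archaea	Aquatic	Brackish sediment	525	208	76.8	41.3
archaea	Aquatic	Freshwater	1540	439	84.7	46.5
archaea	Aquatic	Freshwater sediment	1324	488	79.3	43.9
archaea	Aquatic	Marine	10983	830	95.8	44.5
archaea	Aquatic	Marine sediment	14049	1507	95.0	53.7
archaea	Aquatic	Hydrothermal vent	3797	734	90.4	50.3
archaea	Aquatic	Ice	42	5	95.2	60.0
archaea	Aquatic	Other	772	313	80.7	52.4
archaea	Built	Digesters	4764	483	93.6	36.4
archaea	Built	Food-associated	117	40	80.3	42.5
archaea	Built	Industrial/mining	1245	336	84.4	42.3
archaea	Built	Pollution-associated	716	249	79.2	40.2
archaea	Built	Other	444	111	90.8	63.1
archaea	Plant-associated	Root	200	61	85.5	52.5
archaea	Plant-associated	Surface	0	0	NA	NA
archaea	Plant-associated	Other	22	7	90.9	71.4
archaea	Soil	Agriculture	146	56	80.8	50.0
archaea	Soil	Desert	245	79	77.6	30.4
archaea	Soil	Permafrost	39	20	64.1	30.0
archaea	Soil	Other	2087	516	89.1	55.8
archaea	Host-associated	Vertebrate	5389	454	95.1	41.6
archaea	Host-associated	Arthropod	87	52	58.6	30.8
archaea	Host-associated	Other invertebrate	67	30	73.1	40.0
archaea	Host-associated	Other	54	17	87.0	58.8
archaea	Other	Other	882	249	84.2	44.2
archaea	NoSource	NoSource	2565	559	88.6	47.6
archaea	Total		53546	4252	95.1	38.5
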