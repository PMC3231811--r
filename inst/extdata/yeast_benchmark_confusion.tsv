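# Published confusion counts of yeast gene networks inferred from biclustered
# expression data, evaluated against an integrated protein/genetic interaction
# gold standard over an ordered-pair universe of 635 genes (635*634 = 402590
# pairs). AUROC is the published single-operating-point ROC area (4 decimals).
Method	EdgeCount	TP	FP	TN	FN	AUROC
Gold	2194	2194	0	400396	0	1
ALL	5440	94	5346	395050	2100	0.5148
SAMBA	1611	46	1565	398831	2148	0.5085
ISA	2558	56	2502	397894	2138	0.5097
OPSM	220	12	208	400188	2182	0.5025
Friedman	947	22	925	399471	2172	0.5039
CMSBE	735	20	715	399681	2174	0.5037
K-means	380	13	367	400029	2181	0.5025
Bivisu	1515	13	1502	398894	2181	0.5011
CC	590	3	587	399809	2191	0.5000
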