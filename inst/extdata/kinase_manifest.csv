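moa_label,n_unique_compounds,n_well_datapoints,n_images
PI3K,17,102,838
p38 MAPK,13,76,595
RAF,11,75,607
AURK,10,70,566
CDK,10,74,586
EGFR,9,67,558
ROCK,8,57,463
MEK,6,41,345
GSK,6,40,348
mTOR,6,33,285
Total,96,635,5191
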