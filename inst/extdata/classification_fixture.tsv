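dmr_id	chrom	start	end	direction	expected_category	expected_flagged
D01_plus_d500	chrF	99495	99505	gain	proximal	FALSE
D02_plus_d501	chrF	99494	99504	gain	distal	FALSE
D03_plus_dm100	chrF	100095	100105	gain	proximal	FALSE
D04_plus_dm101	chrF	100096	100106	gain	distal	TRUE
D05_plus_d5000	chrF	94995	95005	gain	distal	FALSE
D06_plus_d5001	chrF	94994	95004	gain	NA	NA
D07_intragenic	chrF	104495	104505	gain	intragenic	FALSE
D08_minus_d500	chrF	300495	300505	gain	proximal	FALSE
D09_minus_d501	chrF	300496	300506	gain	distal	FALSE
D10_minus_dm100	chrF	299895	299905	gain	proximal	FALSE
D11_minus_d5000	chrF	304995	305005	gain	distal	FALSE
D12_intergenic	chrF	500495	500505	gain	intergenic	FALSE
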