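locus	scaffold	scaffold_position	map_position_cM
In2039-2	NW_008988039.1	3280367	0.0
In5039-33	NW_008988039.1	3639340	2.0
R/G	-	-	6.1
In2130-12	NW_008988130.1	908857	8.6
In2130-16	NW_008988130.1	920222	8.6
ZFRI130-16	NW_008988130.1	922094	8.6
In1130-4	NW_008988130.1	154093	10.7
ZFRI130-9	NW_008988130.1	435305	11.0
In2130-5	NW_008988130.1	113643	11.1
In5091-2	NW_008988091.1	15549	13.9
ZFRIt541	NW_008988130.1	916907	17.8
In5126-2	NW_008988126.1	50318	21.0
In5141-1	NW_008988141.1	7013	-
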