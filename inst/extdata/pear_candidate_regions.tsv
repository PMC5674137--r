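scaffold	start	end
NW_008988041.1	3800001	3880000
NW_008988076.1	640001	660000
NW_008988091.1	1	140000
NW_008988126.1	560001	720000
NW_008988130.1	1	300000
NW_008988130.1	500001	580000
NW_008988130.1	760001	960000
NW_008988141.1	1	500000
NW_008988141.1	880001	940000
NW_008988461.1	240001	400000
NW_008988478.1	300001	400000
NW_008988581.1	300001	320000
NW_008989660.1	1	20000
NW_008989715.1	1	20000
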