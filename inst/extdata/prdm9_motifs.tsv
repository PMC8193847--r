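id	pattern
CCTCCCCT	CCTCCCCT
AGGGGAGG	AGGGGAGG
ATCCATG	ATCCATG
CATGGAT	CATGGAT
PRDM9-13mer	CCNCCNTNNCCNC
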