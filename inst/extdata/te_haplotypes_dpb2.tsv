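DPB2	AluDPB2	DPA3	count
*01:01:01	absent	*01	1
*01:01:01	absent	*02	1
*01:01:01	absent	*03	15
*01:01:02	absent	*02	15
*01:01:02	absent	*03	1
*03:01:01	absent	*01	7
*03:01:01	absent	*03	1
*03:01:01	present	*01	15
*03:01:01	present	*03	11
GAP	present	*01	2
GAP	present	*03	3
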