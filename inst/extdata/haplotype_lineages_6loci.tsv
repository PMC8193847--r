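DRB1	DQA1	DQB1	MTCO3P1	DQA2	DQB2	count
*09	*03	*03	*03	*01	*01	2
*07	*02	*02	*04	*01	*01	7
*07	*02	*03	*03	*01	*01	2
*04	*03	*03	*08	*01	*01	8
*04	*03	*03	*10	*01	*01	1
*04	*03	*03	*03	*01	*01	3
*04	*03	*04	*07	*01	*01	6
*08	*06	*03	*03	*01	*01	1
*08	*01	*06	*09	*01	*01	1
*11	*05	*03	*03	*01	*01	6
*11	*01	*05	*03	*01	*01	1
*11	*01	*06	*02	*01	*01	1
*12	*05	*03	GAP	*01	*01	1
*13	*01	*06	*05	*01	*01	4
*13	*01	*06	*02	*01	*01	4
*14	*01	*05	*06	*01	*01	3
*14	*01	*06	GAP	*01	*01	1
*14	*05	*03	GAP	*01	*01	1
*03	*04	*04	*07	*01	*01	1
*03	*05	*02	*01	*01	*01	10
*01	*01	*05	*09	*01	*01	5
*15	*01	*06	*02	*01	*01	7
*15	*01	*06	*03	NotIncluded	NotIncluded	1
*15	*01	*06	*04	*01	*01	3
*16	*01	*05	*03	*01	*01	5
*16	*05	*03	*03	*01	*01	2
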