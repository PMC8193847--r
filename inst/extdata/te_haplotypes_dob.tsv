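AluDOB2	AluDOB1	LTR42.DOB	count
absent	absent	absent	34
absent	absent	present	2
absent	present	absent	21
present	absent	absent	1
present	present	absent	1
present	absent	present	25
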