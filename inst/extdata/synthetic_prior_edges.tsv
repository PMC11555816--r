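source	target
CLN1	CLN2
CLN2	CDC28
CDC5	CDH1
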