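9	21967750	22009312	CDKN2A_B
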