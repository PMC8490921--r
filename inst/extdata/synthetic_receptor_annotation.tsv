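chain	subdomain	start	end	anchor
R	TM3	120	150	134
R	ICL2	151	161	155
R	TM4	162	185	172
R	TM5	210	240	225
R	TM6	250	280	262
R	TM7	285	310	300
R	H8	311	320	313
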