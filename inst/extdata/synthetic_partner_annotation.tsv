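chain	subdomain	start	end	anchor
A	HN	10	35	
A	S3	190	198	
A	h4s6	300	320	
A	H5	330	355	
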