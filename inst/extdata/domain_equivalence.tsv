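domain_name	class
zf-RING_2	RING-class
zf-C3HC4_2	RING-class
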