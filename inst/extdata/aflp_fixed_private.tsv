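group	fpm	ndl_total
turionifera	44	600
minor_SCI	26	604
minor_SCII	8	794
gibba	260	564
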