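motif_id	pattern
CEBP_like	ATTGCGCAAT
VG_module_A	TGASTCAGCA
VG_module_B	CWTATAAAAG
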