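gene	vaf
GNAQ	0.465
SF3B1	0.107
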