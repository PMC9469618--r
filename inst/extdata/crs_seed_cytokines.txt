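# Literature-confirmed CRS-associated cytokines used as seed positives.
# One HGNC-style symbol per line; common alias after the tab where one exists.
CXCL8	IL-8
IL17A
CXCL10	IP-10
CXCL9	MIG
CCL4	MIP-1B
CCL3	MIP-1A
CCL2	MCP-1
IL1A
IL1B
TNF	TNF-alpha
IL2
CSF2	GM-CSF
IL2RA
IL5
IL15
TNFRSF1A
IL4
IL13
IL23A
ANGPT2	ANG2
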