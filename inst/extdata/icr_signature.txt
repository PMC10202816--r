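# name: ICR
IFNG
IRF1
STAT1
IL12B
TBX21
CD8A
CD8B
CXCL9
CXCL10
CCL5
GZMB
GNLY
PRF1
GZMH
GZMA
CD274
PDCD1
CTLA4
FOXP3
IDO1
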