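kind	boundary
min	4.32
interior	6.80
interior	7.32
interior	7.77
interior	8.28
max	11.31
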