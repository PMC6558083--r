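copy_number	count
0	59
1	2958
3	942
4	10
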