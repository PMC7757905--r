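1 2 5
2 3 5
3 4 5
4 5 10
2 3 4
1 6 7
1 7 8
5 6 7
6 8 9
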