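replicate,M,N
1,14.9,10.6
2,14.6,11.2
3,15.4,11.0
4,15.5,10.5
5,16.9,13.2
6,15.2,10.4
7,14.6,11.0
8,12.8,9.5
9,12.3,10.5
10,14.8,10.6
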