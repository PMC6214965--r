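group,uiv,liv,n
1,T2,T12,8
2,T3,T12,10
3,T4,T12,14
4,T2,L1,12
5,T3,L1,8
6,T4,L1,12
7,T3,T11,2
8,T2,T10,1
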