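split,PCR,PLSR,OPLS,EN,SMLR
1,0.18545,0.17693,0.17693,0.14299,0.16524
2,0.26334,0.29223,0.29223,0.27688,0.27026
3,0.22515,0.21094,0.21094,0.18428,0.18602
4,0.27171,0.2548,0.2548,0.26347,0.25632
5,0.20965,0.1905,0.1905,0.22645,0.19704
6,0.33327,0.32225,0.32225,0.3053,0.30847
7,0.23789,0.22115,0.22115,0.24703,0.21343
8,0.25015,0.22506,0.23109,0.24708,0.22395
9,0.18473,0.179,0.179,0.20893,0.18507
10,0.27251,0.26961,0.26961,0.2756,0.26843
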