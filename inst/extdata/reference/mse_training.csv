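split,PCR,PLSR,OPLS,EN,SMLR
1,0.05722,0.01562,0.01562,0.04591,0.02273
2,0.07726,0.02304,0.02304,0.0688,0.0339
3,0.05432,0.00992,0.00992,0.00278,0.01183
4,0.0372,0.02113,0.02113,0.17149,0.03334
5,0.02094,0.01609,0.01609,0.05693,0.0168
6,0.04337,0.02291,0.02291,0.20607,0.03839
7,0.03314,0.02129,0.02129,0.04031,0.01823
8,0.04345,0.01429,0.02959,0.04318,0.02377
9,0.0417,0.03122,0.03122,0.02044,0.02484
10,0.07736,0.01078,0.01078,0.07534,0.02725
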