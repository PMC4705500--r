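split,PCR,PLSR,OPLS,EN,SMLR
1,12.72,12.089,12.089,10.9955,11.972
2,14.6231,14.972,14.972,13.635,14.2868
3,12.8561,12.6299,12.6299,11.5313,12.1758
4,15.1355,14.5171,14.5171,15.3884,14.8151
5,13.0635,12.3538,12.3538,13.8607,12.8326
6,14.6371,13.954,13.954,13.9972,13.9497
7,15.2913,14.5146,14.5146,14.8474,14.132
8,14.4245,14.0604,14.3823,13.9682,13.9149
9,12.1609,11.7033,11.7033,12.918,12.0041
10,14.4008,13.6742,13.6742,14.2981,13.9341
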