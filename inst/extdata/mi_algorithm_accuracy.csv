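Subject,iQSA,FDCSP,MEMD-SI-BCI,SR-FBCSP
1,0.8543,0.9166,0.9236,0.8924
2,0.8296,0.6805,0.5833,0.5936
3,0.8273,0.9722,0.9167,0.9581
4,0.8509,0.7222,0.6389,0.7073
5,0.7879,0.7222,0.5903,0.7810
6,0.8284,0.7153,0.6736,0.6998
7,0.8172,0.8125,0.6042,0.8824
8,0.8466,0.9861,0.9653,0.9532
9,0.8425,0.9375,0.6667,0.9192
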