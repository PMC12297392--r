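fold,accuracy,dice,auc
1,0.9456,0.9113,0.9386
2,0.9461,0.9146,0.9396
3,0.9481,0.9122,0.9365
4,0.9442,0.9066,0.9311
5,0.9527,0.9191,0.9419
6,0.9503,0.9173,0.9391
7,0.9474,0.9134,0.9381
8,0.9506,0.9206,0.9441
9,0.9496,0.9157,0.9370
10,0.9520,0.9204,0.9403
11,0.9484,0.9148,0.9377
12,0.9493,0.9162,0.9388
13,0.9510,0.9183,0.9410
14,0.9513,0.9195,0.9404
15,0.9525,0.9213,0.9423
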