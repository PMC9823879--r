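fold,TP,FN,TN,FP
1,155,25,148,32
2,159,21,152,28
3,154,26,161,19
4,168,12,161,19
5,156,24,160,20
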