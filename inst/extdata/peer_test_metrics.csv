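metric,unet,pspnet,fpnnet,vit,tatha
loss,0.2127,0.1912,0.2163,0.2789,0.152977
accuracy,0.9125,0.9345,0.9053,0.8972,0.962158
map,0.3867,0.4078,0.4021,0.3624,0.447977
auc,0.9148,0.9382,0.9225,0.8967,0.950778
specificity,0.9512,0.9635,0.9459,0.9278,0.977011
sensitivity,0.8146,0.8394,0.8001,0.7721,0.97362
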