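network,class,tp,fp,fn,tn,fpr_pct,tpr_pct,precision_pct,accuracy_pct
net1,1,1017,33,8,4338,0.8,99.2,96.9,99.2
net1,2,471,4,4,4917,0.1,99.2,99.2,99.9
net1,3,279,2,2,5113,0.0,99.3,99.3,99.9
net1,4,1828,28,8,3532,0.8,99.6,98.5,99.3
net1,5,1545,19,4,3828,0.5,99.7,98.8,99.6
net1,6,162,12,72,5150,0.2,69.2,93.1,98.4
net3,1,1017,31,8,4340,0.7,99.2,97.0,99.3
net3,2,471,5,3,4917,0.1,99.4,98.9,99.9
net3,3,280,2,1,5113,0.0,99.6,99.3,99.9
net3,4,1823,12,13,3548,0.3,99.3,99.3,99.5
net3,5,1541,19,8,3828,0.5,99.5,98.8,99.5
net3,6,180,19,54,5143,0.4,76.9,90.5,98.6
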