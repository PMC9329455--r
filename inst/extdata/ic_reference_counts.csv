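network,component_type,tp,fp,fn,tn,fpr_pct,tpr_pct,precision_pct,accuracy_pct
net1B,artifact,967,49,39,577,7.8,96.1,95.2,94.6
net1B,signal,577,39,49,967,3.9,92.2,93.7,94.6
net2B,artifact,945,68,61,558,10.9,93.9,93.3,92.1
net2B,signal,558,61,68,945,6.1,89.1,90.1,92.1
net3B,artifact,937,65,69,561,10.4,93.1,93.5,91.8
net3B,signal,561,69,65,937,6.9,89.6,89.0,91.8
net4B,artifact,938,62,68,564,9.9,93.2,93.8,92.0
net4B,signal,564,68,62,938,6.8,90.1,89.2,92.0
net5B,artifact,929,64,77,562,10.2,92.3,93.6,91.4
net5B,signal,562,77,64,929,7.7,89.8,87.9,91.4
net6B,artifact,876,53,130,573,8.5,87.1,94.3,88.8
net6B,signal,573,130,53,876,12.9,91.5,81.5,88.8
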