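group,method,n,mean_diff,sd_diff
normal,auc,32,0.50,7.57
normal,patlak,32,1.51,7.13
pathological,auc,56,-0.37,6.78
pathological,patlak,56,-0.76,5.84
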