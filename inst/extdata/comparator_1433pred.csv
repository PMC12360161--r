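model,BA,Pr,Rc,Sp
14-3-3-Pred MLP,60,74,71,48
14-3-3-Pred SVM,61,89,29,93
14-3-3-Pred PSSM,60,74,71,48
14-3-3-Pred Ensemble,65,82,64,67
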