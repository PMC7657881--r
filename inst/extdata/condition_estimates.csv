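condition,mode,speed,criterion_z,criterion_lo,criterion_hi,sensitivity_z,sensitivity_lo,sensitivity_hi,auc,auc_lo,auc_hi
cospeech (original),cospeech,original,-0.22,-0.30,-0.15,0.33,0.25,0.41,0.66,0.64,0.68
cospeech (sped-up),cospeech,sped-up,-0.01,-0.09,0.07,0.22,0.14,0.31,0.68,0.66,0.70
colaughter (original),colaughter,original,-0.03,-0.13,0.06,0.70,0.62,0.79,0.75,0.73,0.77
colaughter (sped-up),colaughter,sped-up,0.16,0.07,0.26,0.69,0.60,0.79,0.75,0.73,0.77
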