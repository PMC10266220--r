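cpg_id,chrom,pos,gene,feature,mean_treated_disc,mean_untreated_disc,delta_beta_disc,p_disc,mean_treated_repl,mean_untreated_repl,delta_beta_repl,p_repl,p_combined
cg01028142,2,7004578,CMPK2,Body,0.77,0.86,-0.09,8.73e-14,0.75,0.83,-0.08,3.79e-15,3.31e-28
cg24678928,4,169240829,DDX60,TSS1500,0.70,0.80,-0.10,1.52e-09,0.70,0.79,-0.09,9.35e-12,1.42e-20
cg13452062,1,79088559,IFI44L,5'UTR,0.50,0.77,-0.27,2.06e-10,0.53,0.77,-0.23,2.11e-13,4.34e-23
cg08888522,2,163172908,IFIH1,Body,0.81,0.89,-0.07,1.60e-10,0.83,0.88,-0.05,4.29e-10,6.86e-20
cg05552874,10,91153143,IFIT1,Body,0.46,0.57,-0.11,3.00e-10,0.49,0.54,-0.05,3.08e-05,9.25e-15
cg06188083,10,91093005,IFIT3,Body,0.36,0.45,-0.08,3.39e-08,0.35,0.43,-0.08,4.13e-11,1.40e-18
cg26312951,21,42797847,MX1,TSS200;5'UTR,0.20,0.28,-0.08,1.25e-10,0.19,0.27,-0.08,2.50e-13,3.12e-23
cg26505274,12,121474114,OASL,Body,0.72,0.63,0.09,2.45e-10,0.69,0.60,0.09,2.33e-10,5.71e-20
cg22930808,3,122281881,PARP9,5'UTR,0.49,0.61,-0.12,6.06e-09,0.48,0.58,-0.10,2.81e-10,1.70e-18
cg06981309,3,146260954,PLSCR1,5'UTR,0.29,0.38,-0.09,3.43e-09,0.30,0.34,-0.04,2.20e-05,7.55e-14
cg10549986,2,7018153,RSAD2,1stExon,0.11,0.18,-0.07,4.17e-08,0.14,0.20,-0.06,1.88e-09,7.83e-17
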