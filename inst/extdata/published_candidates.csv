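gene_symbol,pct_alp,p_bound,table
H2-Ob,231.79,0.05,1
Ifna9,205.22,0.05,1
Icam5,193.19,0.01,1
H2-DMa,192.48,0.01,1
Il13ra2,187.73,0.05,1
Hgfac,12.52,0.001,2
Ifna13,14.40,0.001,2
Idi1,15.06,0.001,2
Icos,17.07,0.001,2
Ssh1,18.38,0.001,2
Hmbs,19.25,0.001,2
Ube2k,19.83,0.001,2
Igfbp1,20.25,0.001,2
Glipr1,21.09,0.001,2
Hspa5,21.38,0.001,2
Hip1,21.74,0.001,2
Ifi30,22.19,0.001,2
Herpud1,22.43,0.001,2
Herc2,22.60,0.001,2
Golga5,22.68,0.001,2
Hdac7,22.85,0.001,2
Gnmt,22.92,0.001,2
Hal,23.37,0.001,2
Hmga2,23.53,0.001,2
Hcrtr1,25.64,0.001,2
Hey2,26.08,0.001,2
Hmgn2,27.29,0.001,2
Hspb1,27.62,0.001,2
Sap30bp,28.38,0.001,2
Hrc,28.65,0.01,2
Ifngr2,29.00,0.001,2
Hus1,29.61,0.001,2
Hoxb5,29.71,0.001,2
Ifit3,29.78,0.001,2
Il11,29.79,0.001,2
Hrasls,29.82,0.01,2
Hat1,30.15,0.01,2
Golgb1,30.26,0.001,2
Lilrb4,30.49,0.001,2
Hp,30.75,0.001,2
Hfe,30.79,0.001,2
Hcn2,30.92,0.001,2
Herc1,31.25,0.001,2
Hrg,31.67,0.001,2
Hdac2,31.72,0.001,2
H2-T23,31.89,0.001,2
Hoxc4,31.92,0.001,2
Icam1,33.13,0.001,2
Hpcal1,33.40,0.001,2
Ifi204,34.07,0.01,2
Hivep2,34.29,0.01,2
Ifnar1,34.37,0.001,2
Hps3,35.06,0.001,2
Ifit2,36.49,0.001,2
Hsf2,37.11,0.01,2
Hdac3,37.29,0.001,2
Ifna4,38.04,0.001,2
Hoxd12,38.15,0.01,2
Gpr135,38.43,0.001,2
Hgf,38.54,0.001,2
Hdac11,38.70,0.001,2
Hsd11b2,38.72,0.01,2
Glo1,38.83,0.001,2
Hnf4g,39.32,0.001,2
Hesx1,39.62,0.01,2
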