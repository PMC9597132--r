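model,label,chisq,df,cfi,rmsea,srmr,aic,bic
1,Unidimensional model (Alex),29912.4,170,0.768,0.050,0.084,29572.4,28016.5
2,Two-dimensional model (DIF/DDF-EOT),16757.7,169,0.871,0.038,0.056,16419.7,14873.0
3a,Original three-dimensional model (DIF-DDF-EOT),8424.2,167,0.936,0.027,0.041,8090.2,6561.8
3b,Alternative three-dimensional model (DIF/DDF-PT-IOE),16635.4,167,0.872,0.038,0.055,16301.4,14772.9
3c,Alternative three-dimensional model (DIF/DDF-EOT-IOE),22216.9,167,0.828,0.044,0.073,21882.9,20354.4
4,Four-dimensional model (DIF-DDF-PT-IOE),8274.7,164,0.937,0.027,0.040,7946.7,6445.8
5,Bifactor model with three original factors as nested factors,6159.8,150,0.953,0.024,0.026,5859.8,4487.0
6,Original three-dimensional model + nested method factor,1756.5,162,0.988,0.012,0.013,1432.5,-50.2
7,Original three-dimensional model + correlated residuals,1753.9,157,0.988,0.012,0.013,1439.9,3.0
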