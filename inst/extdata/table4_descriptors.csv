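compound,d,S_vdW,S_wat,A_vdW,mu_D,dG_exp,dG_pred,dG_res
7a,1.03,328.65,550.09,304.36,1.55,-0.47,-1.02,0.55
7b,1.01,356.64,591.24,335.12,2.16,-2.64,-1.95,-0.69
7c,1.05,343.45,565.21,317.53,1.69,-0.78,-1.16,0.38
7d,1.07,347.51,564.98,328.09,6.67,-2.64,-2.78,0.14
7e,1.14,354.30,588.50,329.31,1.58,-0.15,-1.19,1.04
7f,0.97,345.98,575.78,317.19,3.13,-1.06,-0.33,-0.73
8a,1.03,341.05,554.61,309.59,1.64,-0.15,-0.30,0.15
8b,1.09,365.46,594.35,340.35,2.07,-2.64,-1.75,-0.89
8c,1.03,353.34,575.63,322.77,1.39,-0.39,-0.53,0.14
8d,1.05,356.39,568.95,333.33,4.69,-2.72,-2.54,-0.18
8e,1.12,363.84,588.79,334.55,1.55,-0.72,-1.02,0.3
8f,0.97,356.88,581.58,322.42,0.36,-0.16,0.24,0.4
9d,1.11,491.05,756.77,345.12,4.60,-2.64,-2.79,0.15
9e,1.18,502.38,783.44,459.34,1.64,-0.47,-0.49,0.02
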