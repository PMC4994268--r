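compound,sigma1_ki,sigma2_ki,ratio
7a,2.96±0.52,21.64±8.07,5
7b,>434,>854,2
7c,5.98±0.41,554.03±34.22,93
7d,>434,>854,2
7e,1.40±0.5,>854,610
7f,11.58±0.26,151.47±7.79,13
8a,1.41±0.22,>854,606
8b,>434,>854,2
8c,2.49±0.24,>854,343
8d,526.53±69,>854,2
8e,5.22±0.3,>854,164
8f,1.45±0.4,>854,589
9d,>434,>854,2
9e,2.95±0.57,>854,289
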