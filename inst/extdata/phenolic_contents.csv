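peak,compound,class,area_pct,content_mg_g,content_sd
1,3-O-caffeoyl-5-O-p-coumaroylquinic acid,hydroxycinnamic_acid,2.21,0.25,0.01
2,coumaroyloleuropein,hydroxycinnamic_acid,9.69,0.42,0.03
3,luteolin-O-glucoside,flavonoid,2.49,0.16,0.01
4,"3,5-dicaffeoylquinic acid monohydrate",hydroxycinnamic_acid,4.34,0.20,0.00
5,"3,5-dicaffeoylquinic acid",hydroxycinnamic_acid,5.43,0.24,0.00
6,gallic acid monohydrate,hydroxybenzoic_acid,2.80,0.31,0.02
7,shikimic acid isomer,hydroxybenzoic_acid,3.07,0.34,0.02
8,methoxyoleuropein isomer,hydroxycinnamic_acid,2.97,0.14,0.01
9,luteolin,flavonoid,19.75,1.61,0.11
10,prenyl-dimethoxy-caffeoyl-p-coumaric acid,hydroxycinnamic_acid,20.88,0.89,0.06
11,apigenin,flavonoid,9.12,0.57,0.02
12,chrysoeriol,flavonoid,2.23,0.13,0.01
13,tricin,flavonoid,3.95,0.24,0.00
17,acacetin,flavonoid,11.09,0.92,0.02
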