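c22orf32.fa	3edb06a79c7ce6156ea2634cf4190208
casq1.fa	a39ba2075e02d26d708fabd17e586f09
casq2_ag.fa	eda6f57e18cb27911313e5c7f7a75c14
casq2_de_plus.fa	21e240751adfb6836d16a9c486f8a487
casq2_de.fa	78dcc7755ea0a652be4f2223e17b041a
casq2_gau_gac.fa	9cde13ce4ad0750b87b45a0357975dd2
casq2_scramble.fa	fa759e146b86b85acc7c035427268802
casq2_wt.fa	dca82b3e5cebd8843f73317b3251250b
ccdc36.fa	c12a8d0edea36a78514a15aaf6c7e72f
nt5c2.fa	ac5702ebf659c168f631f25892fa4e6b
tmem97.fa	e664fcd357ca8fdc74bed51dc29ed07d
wdr45.fa	42fc06c45d7617e4e2cd4dea3e2a6f5a
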