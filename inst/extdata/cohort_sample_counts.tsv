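cohort	n_samples	n_cancer	n_normal	n_genes	histopathology	has_normal
Bertilsson	156	116	40	14149	yes	yes
Chen	136	65	71	12497	yes	yes
Taylor	160	131	29	18294	no	yes
TCGA	549	497	52	20504	no	yes
Prensner	116	78	38	23712	no	yes
Sboner	281	281	0	6102	no	no
Erho	545	545	0	17163	no	no
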