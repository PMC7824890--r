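file	md5
sirtuin_catalog.tsv	ecbd8d6c9894ae46d3feeddb324f613a
sirt1_locus.fa	5238717133087378bdca9ccd93f9a477
sirt1_locus.gff3	50617047b65dd418a4c7ced3d6f4d027
mouse_sirt1_locus.fa	e9302ff359b62d13c417c2ecbd31efe9
mouse_sirt1_locus.gff3	d8e2a472a6c30e39428fca3ec115eec1
sirt1_signals.tsv	6d8676a41053edbe5df1d5ebc276c24e
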