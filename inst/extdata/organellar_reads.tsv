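# Published aggregate EST read counts per genomic compartment for the
# iron-limited (fe_minus) and iron-replete (fe_plus) cDNA libraries.
gene_id	count_fe_minus	count_fe_plus	compartment
chloroplast_total	2026	14931	chloroplast
mitochondrial_total	31261	18136	mitochondrial
rRNA_18S	1154	2691	rRNA_18S
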