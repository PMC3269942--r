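taxon_id	name
9606	Homo sapiens
10090	Mus musculus
10116	Rattus norvegicus
7227	Drosophila melanogaster
6239	Caenorhabditis elegans
4932	Saccharomyces cerevisiae
559292	Saccharomyces cerevisiae S288C
3702	Arabidopsis thaliana
7955	Danio rerio
8355	Xenopus laevis
9913	Bos taurus
9031	Gallus gallus
83333	Escherichia coli K-12
562	Escherichia coli
224308	Bacillus subtilis
4896	Schizosaccharomyces pombe
9823	Sus scrofa
9615	Canis lupus familiaris
9986	Oryctolagus cuniculus
39947	Oryza sativa
4577	Zea mays
44689	Dictyostelium discoideum
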