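{"version":1,"feature_order":["match_exact","match_partial","vote_total","rule_Species","rule_Cell","rule_PPI","rule_History","rule_FullNameAcronym","rule_Tissue","rule_Domain","rule_Family","rule_Mass","rule_GeneOntology","rule_ChromosomeLocation","rule_SequenceLength","rule_RSNumber","freq_article","freq_results_pct","loc_title","loc_abstract","loc_abstract_last_n1","loc_first_section","loc_first_section_last_n2","loc_results","loc_other","loc_last_section","loc_section_title","loc_appendix","loc_figure_caption","loc_table_caption","keyword_match","fullname_abbrev_match"],"weights":{"match_exact":-3.95697654737862e-25,"match_partial":0,"vote_total":2.64049085229012,"rule_Species":-3.35630196036062,"rule_Cell":0,"rule_PPI":0,"rule_History":-1.90219514095228,"rule_FullNameAcronym":-1.80832937261752,"rule_Tissue":0,"rule_Domain":-1.72942230416316,"rule_Family":0,"rule_Mass":0,"rule_GeneOntology":2.32723099736797,"rule_ChromosomeLocation":0,"rule_SequenceLength":0,"rule_RSNumber":0,"freq_article":-1.55309832768438,"freq_results_pct":0.160626565903853,"loc_title":1.46724405000669,"loc_abstract":5.50121791211748e-26,"loc_abstract_last_n1":3.33097463098155e-27,"loc_first_section":8.74541131204552e-26,"loc_first_section_last_n2":1.7416594423355,"loc_results":-5.70701131849128e-26,"loc_other":-1.7416594423355,"loc_last_section":-1.57879685121393,"loc_section_title":0,"loc_appendix":0,"loc_figure_caption":-1.57879685121393,"loc_table_caption":0,"keyword_match":1.46724405000669,"fullname_abbrev_match":-1.80832937261752},"bias":12.4053237773284,"calibration":{"a":1,"b":0}}
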