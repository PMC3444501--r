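# Published summary counts from the 2011 DrugBank/KEGG snapshot behind the
# approved-CVD-drug study set: numerators are drugs/targets/pathways covered
# by the 33 selected key pathways, denominators the pathway-mapped totals
# (133 drugs, 131 of 188 targets, 120 target-containing pathways).
quantity	numerator	denominator
drugs_covered	129	133
targets_covered	103	131
pathways_selected	33	120
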