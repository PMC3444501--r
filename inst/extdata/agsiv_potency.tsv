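# Published half-maximal concentrations (nM) for astragaloside IV (AGS-IV)
# against cardiovascular targets, with the reference inhibitor assayed or
# cited alongside. One row per assay; test and reference share the unit.
assay	level	test_value	reference_value	unit	reference_name
calcineurin_inhibition	protein	403	8.3	nM	cyclosporin A
ace_inhibition	protein	268	1.94	nM	enalapril
ldh_release_inhibition	cellular	1357	365	nM	cyclosporin A
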