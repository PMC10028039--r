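name	motif	backbone	tail
KR12	WCGCCWWCA		IndoleSecoCBI
CCC-002	WGGCWCCCA		IndoleSecoCBI
CCC-003		Ac-NH-PyPyPyPybPyPyPy-g-ImImbImImPy-COOH	IndoleSecoCBI
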