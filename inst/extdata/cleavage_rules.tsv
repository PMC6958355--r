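enzyme	variant	kind	P4	P3	P2	P1	P1p	P2p	P3p	P4p	note
Pa		pattern	*	*	*	FL	*	*	*	*	pepsin pH<1.8, cleaves C-terminal to F/L
Pa		pattern	*	*	*	*	FL	*	*	*	pepsin pH<1.8, cleaves N-terminal to F/L
Pb		pattern	*	*	*	FLWY	*	*	*	*	pepsin pH>2, cleaves C-terminal to F/L/W/Y
Pb		pattern	*	*	*	*	FLWY	*	*	*	pepsin pH>2, cleaves N-terminal to F/L/W/Y
T		pattern	*	*	*	KR	^P	*	*	*	trypsin, K/R not before P
T		pattern	*	*	W	K	P	*	*	*	trypsin, WK^P cleaved despite proline
T		pattern	*	*	M	R	P	*	*	*	trypsin, MR^P cleaved despite proline
T		exception	*	*	C	K	D	*	*	*	Keil exception
T		exception	*	*	D	K	D	*	*	*	Keil exception
T		exception	*	*	C	K	H	*	*	*	Keil exception
T		exception	*	*	C	K	Y	*	*	*	Keil exception
T		exception	*	*	C	R	K	*	*	*	Keil exception
T		exception	*	*	R	R	H	*	*	*	Keil exception
T		exception	*	*	R	R	R	*	*	*	Keil exception
CT	low	pattern	*	*	*	FLY	^P	*	*	*	chymotrypsin low specificity
CT	low	pattern	*	*	*	W	^MP	*	*	*	chymotrypsin low specificity
CT	low	pattern	*	*	*	M	^PY	*	*	*	chymotrypsin low specificity
CT	low	pattern	*	*	*	H	^DMPW	*	*	*	chymotrypsin low specificity
CT	high	pattern	*	*	*	FY	^P	*	*	*	chymotrypsin high specificity
CT	high	pattern	*	*	*	W	^MP	*	*	*	chymotrypsin high specificity
E		pattern	DE	DE	DE	K	*	*	*	*	enterokinase, acidic run then K
Th		pattern	*	*	G	R	G	*	*	*	thrombin G-R/G
Th		pattern	AFGILTVM	AFGILTVW	P	R	^DE	^DE	*	*	thrombin extended context
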