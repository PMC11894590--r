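name	type	P6	P5	P4	P3	P2	P1	P1p	P2p
Arg-C proteinase	cleave	-	-	-	-	-	R	-	-
Asp-N endopeptidase	cleave	-	-	-	-	-	-	D	-
Asp-N endopeptidase + N-terminal Glu	cleave	-	-	-	-	-	-	DE	-
BNPS-Skatole	cleave	-	-	-	-	-	W	-	-
Caspase1	cleave	-	-	FWYL	-	HAT	D	{PEDQKR}	-
Caspase2	cleave	-	-	D	V	A	D	{PEDQKR}	-
Caspase3	cleave	-	-	D	M	Q	D	{PEDQKR}	-
Caspase4	cleave	-	-	L	E	V	D	{PEDQKR}	-
Caspase5	cleave	-	-	LW	E	H	D	-	-
Caspase6	cleave	-	-	V	E	HI	D	{PEDQKR}	-
Caspase7	cleave	-	-	D	E	V	D	{PEDQKR}	-
Caspase8	cleave	-	-	IL	E	T	D	{PEDQKR}	-
Caspase9	cleave	-	-	L	E	H	D	-	-
Caspase10	cleave	-	-	I	E	A	D	-	-
Chymotrypsin-high specificity	cleave	-	-	-	-	-	FY	{P}	-
Chymotrypsin-high specificity	cleave	-	-	-	-	-	W	{MP}	-
Chymotrypsin-low specificity	cleave	-	-	-	-	-	FLY	{P}	-
Chymotrypsin-low specificity	cleave	-	-	-	-	-	W	{MP}	-
Chymotrypsin-low specificity	cleave	-	-	-	-	-	M	{PY}	-
Chymotrypsin-low specificity	cleave	-	-	-	-	-	H	{DMPW}	-
Clostripain	cleave	-	-	-	-	-	R	-	-
CNBr	cleave	-	-	-	-	-	M	-	-
Enterokinase	cleave	-	-	DE	DE	DE	K	-	-
Factor Xa	cleave	-	-	AFGILTVM	DE	G	R	-	-
Formic acid	cleave	-	-	-	-	-	D	-	-
Glutamyl endopeptidase	cleave	-	-	-	-	-	E	-	-
Granzyme B	cleave	-	-	I	E	P	D	-	-
Hydroxylamine	cleave	-	-	-	-	-	N	G	-
Iodosobenzoic acid	cleave	-	-	-	-	-	W	-	-
LysC	cleave	-	-	-	-	-	K	-	-
LysN	cleave	-	-	-	-	-	-	K	-
NTCB (2-nitro-5-thiocyanobenzoic acid)	cleave	-	-	-	-	-	-	C	-
Pepsin (pH1.3)	cleave	-	-	-	{HKR}	{P}	{R}	FL	{P}
Pepsin (pH1.3)	cleave	-	-	-	{HKR}	{P}	FL	-	{P}
Pepsin (pH>2)	cleave	-	-	-	{HKR}	{P}	{R}	FLWY	{P}
Pepsin (pH>2)	cleave	-	-	-	{HKR}	{P}	FLWY	-	{P}
Proline-endopeptidase	cleave	-	-	-	-	HKR	P	{P}	-
Proteinase K	cleave	-	-	-	-	-	AEFILTVWY	-	-
Staphylococcal peptidase I	cleave	-	-	-	-	{E}	E	-	-
Tobacco etch virus protease	cleave	E	-	-	Y	-	Q	GS	-
Thermolysin	cleave	-	-	-	-	-	{DE}	AFILMV	{P}
Thrombin	cleave	-	-	-	-	G	R	G	-
Thrombin	cleave	-	-	AFGILTVM	AFGILTVWA	P	R	{DE}	{DE}
Trypsin	cleave	-	-	-	-	-	KR	{P}	-
Trypsin	cleave	-	-	-	-	W	K	P	-
Trypsin	cleave	-	-	-	-	M	R	P	-
Trypsin	exception	-	-	-	-	CD	K	D	-
Trypsin	exception	-	-	-	-	C	K	HY	-
Trypsin	exception	-	-	-	-	C	R	K	-
Trypsin	exception	-	-	-	-	R	R	HR	-
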