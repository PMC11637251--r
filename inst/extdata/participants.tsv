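Participant_ID	Gender	Age	Group	MMSE
001	F	57	A	16
002	F	78	A	22
003	M	70	A	14
004	F	67	A	20
005	M	70	A	22
006	F	61	A	14
007	F	79	A	20
008	M	62	A	16
009	F	77	A	23
010	M	69	A	20
011	M	71	A	22
012	M	63	A	18
013	F	64	A	20
014	M	77	A	14
015	M	61	A	18
016	F	68	A	14
017	F	61	A	6
018	F	73	A	23
019	F	62	A	14
020	M	71	A	4
021	M	71	A	22
022	F	68	A	20
023	M	60	A	16
024	F	69	A	20
025	F	79	A	20
026	F	61	A	18
027	F	67	A	16
028	M	49	A	20
029	F	53	A	16
030	F	56	A	20
031	F	67	A	22
032	F	59	A	20
033	F	72	A	20
034	F	75	A	18
035	F	57	A	22
036	F	58	A	9
037	M	57	C	30
038	M	62	C	30
039	M	70	C	30
040	M	61	C	30
041	F	77	C	30
042	M	74	C	30
043	M	72	C	30
044	F	64	C	30
045	F	70	C	30
046	M	63	C	30
047	F	70	C	30
048	M	65	C	30
049	F	62	C	30
050	M	68	C	30
051	F	75	C	30
052	F	73	C	30
053	M	70	C	30
054	M	78	C	30
055	M	67	C	30
056	F	64	C	30
057	M	64	C	30
058	M	62	C	30
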