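label	isoform	start	end	sequence
NfL_299-318	NfL	299	318	RAAKDEVSESRRLLKAKTLEIEAC
NfL_101-107	NfL	101	107
NfL_117-126	NfL	117	126
NfL_165-172	NfL	165	172
NfL_284-293	NfL	284	293
NfL_324-360	NfL	324	360
NfL_318-330	NfL	318	330
NfL_331-357	NfL	331	357
NfL_24-169	NfL	24	169
NfM_327-334	NfM	327	334
NfM_383-440	NfM	383	440
NfH_1-476	NfH	1	476
NfH_476-986	NfH	476	986
NfH_476-1026	NfH	476	1026
NfH_835-1026	NfH	835	1026
NfH_852-986	NfH	852	986
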