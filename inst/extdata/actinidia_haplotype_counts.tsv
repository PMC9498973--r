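hap_id	species	n_samples	accession
MH1	Actinidia eriantha	46	OK036712
MH2	Actinidia eriantha	1	OK036713
MH3	Actinidia eriantha	5	OK036795
MH4	Actinidia eriantha	2	OK036796
MH5	Actinidia eriantha	1	OK036797
MH6	Actinidia eriantha	1	MG714287
MH7	Actinidia eriantha	1	KP314044
MH8	Actinidia eriantha	1	KP314039
MH9	Actinidia eriantha	1	KP314038
GZ1	Actinidia polygama	12	OK036798
GZ2	Actinidia polygama	3	KP314060
GZ3	Actinidia polygama	1	KP314051
GZ4	Actinidia polygama	2	KC519766
GZ5	Actinidia polygama	1	AF323796
HL1	Actinidia melanandra	11	OK036799
HL2	Actinidia melanandra	1	AF443211
HL3	Actinidia melanandra	1	MG714282
HL4	Actinidia melanandra	1	AF323808
WD1	Actinidia arguta	10	OK036800
WD2	Actinidia arguta	1	KP314061
WD3	Actinidia arguta	1	KP314034
WD4	Actinidia arguta	4	AF323836
WD5	Actinidia arguta	1	AF323835
WD6	Actinidia arguta	1	KP314062
ZH1	Actinidia chinensis	21	OK036801
ZH2	Actinidia chinensis	1	OK036802
ZH3	Actinidia chinensis	1	KC832305
ZH4	Actinidia chinensis	1	KC832307
ZH5	Actinidia chinensis	1	KC832316
ZH6	Actinidia chinensis	2	KC519784
DE1	Actinidia valvata	10	OK036803
DE2	Actinidia valvata	1	MG714283
DE3	Actinidia valvata	1	MG714281
DE4	Actinidia valvata	3	KC519764
DE5	Actinidia valvata	1	AF323842
CY1	Actinidia hemsleyana	11	OK036804
CY2	Actinidia hemsleyana	3	KC519783
CY3	Actinidia hemsleyana	1	AF323802
YS1	Actinidia callosa	10	OK036805
YS2	Actinidia callosa	1	AF323803
YS3	Actinidia callosa	1	MH808396
YS4	Actinidia callosa	1	MH808395
YS5	Actinidia callosa	1	KC519753
YS6	Actinidia callosa	1	KC519739
YS7	Actinidia callosa	1	AF323804
YS8	Actinidia callosa	1	AF323828
ST1	Saurauia tristyla	1	KP092594
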