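channel_name	group_name
Fp1	Fp
Fpz	Fp
Fp2	Fp
AF7	AFL
AF3	AFL
AF4	AFR
AF8	AFR
F7	FL
F5	FL
F3	FL
F1	Fz
Fz	Fz
F2	Fz
F4	FR
F6	FR
F8	FR
FC5	FCL
FC3	FCL
FC1	FCL
FC2	FCR
FC4	FCR
FC6	FCR
T9	TL
FT7	TL
T7	TL
FT8	TR
T8	TR
T10	TR
C5	CL
C3	CL
C1	CL
Cz	Cz
C2	CR
C4	CR
C6	CR
TP7	TPL
TP8	TPR
CP5	CPL
CP3	CPL
CP1	CPL
CP2	CPR
CP4	CPR
CP6	CPR
P9	PL
P7	PL
P5	PL
P3	PL
P1	PL
P2	PR
P4	PR
P6	PR
P8	PR
P10	PR
CPz	Pz
Pz	Pz
PO7	POL
PO3	POL
PO4	POR
PO8	POR
POz	O
O1	O
Oz	O
O2	O
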